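# Independent brute-force oracle for the four whole-graph statistics:
# Floyd-Warshall distances and direct evaluation of the printed
# formulas, written against plain edge lists so it shares no code with
# the production path (which uses igraph's shortest-path routines).

# Floyd-Warshall all-pairs distances from a two-column edge matrix.
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  if (NROW(edges) > 0) {
    for (r in seq_len(NROW(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      D[a, b] <- 1; D[b, a] <- 1
    }
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Direct evaluation of the four statistics from nodes + edge list.
oracle_profile <- function(nodes, edges) {
  n <- length(nodes)
  deg <- stats::setNames(numeric(n), nodes)
  if (NROW(edges) > 0) {
    tab <- table(c(edges[, 1], edges[, 2]))
    deg[names(tab)] <- as.numeric(tab)
  }
  ad <- sum(deg) / n
  D <- fw_distances(nodes, edges)
  finite <- is.finite(D); diag(finite) <- FALSE
  aspl <- if (sum(finite) == 0) NA_real_ else sum(D[finite]) / sum(finite)
  dc <- if (n < 3) 0 else sum(max(deg) - deg) / ((n - 1) * (n - 2))
  # Wasserman-Faust component-scaled closeness
  clo <- numeric(n)
  for (i in seq_len(n)) {
    reach <- sum(finite[i, ])
    clo[i] <- if (reach == 0) 0 else
      (reach / (n - 1)) * (reach / sum(D[i, finite[i, ]]))
  }
  cc <- if (n < 3) 0 else
    sum(max(clo) - clo) / ((n - 1) * (n - 2) / (2 * n - 3))
  list(ad = ad, aspl = aspl, dc = dc, cc = cc)
}

# uniform G(n, m) sampler sharing no code with random_network()
oracle_gnm_edges <- function(labels, m) {
  n <- length(labels)
  pairs <- utils::combn(n, 2)
  idx <- sample.int(ncol(pairs), m)
  cbind(labels[pairs[1, idx]], labels[pairs[2, idx]])
}

# robustness index by direct formula from node/edge lists
oracle_ri <- function(nodes, edges, targets) {
  before <- oracle_profile(nodes, edges)
  keep <- setdiff(nodes, targets)
  if (NROW(edges) > 0) {
    ek <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
  } else ek <- edges
  after <- oracle_profile(keep, ek)
  rel <- function(b, a) {
    if (is.na(b) || is.na(a) || b == 0) NA_real_ else (a - b) / b
  }
  c(ad = rel(before$ad, after$ad), aspl = rel(before$aspl, after$aspl),
    dc = rel(before$dc, after$dc), cc = rel(before$cc, after$cc))
}

# igraph fixtures used across tests
named_graph <- function(edges, isolates = character(0)) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (length(isolates) > 0) g <- igraph::add_vertices(g, length(isolates),
                                                      name = isolates)
  g
}

k4 <- function() {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- c("A", "B", "C", "D")
  g
}

path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  g
}

star_graph <- function(n) {
  g <- igraph::make_star(n, mode = "undirected")
  igraph::V(g)$name <- c("HUB", paste0("L", seq_len(n - 1)))
  g
}

# random named graph for property tests (structure built with igraph;
# all statistics on it are checked against the plain-R oracle)
rand_named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

graph_edges <- function(g) igraph::as_edgelist(g)

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
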