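# Per-pathological-process functional subnetworks: induced PPI
# subgraphs on each cluster's genes, with edges shared by too many
# subnetworks removed so that each subnetwork stays process-specific.

#' Build functional subnetworks from cluster assignments
#'
#' For each cluster (pathological process), induces the PPI subgraph
#' on that cluster's genes. Any interaction occurring in more than
#' `max_occurrence` subnetworks is then deleted from every subnetwork
#' (the pruned collection forms the final process-specific
#' subnetworks); the removed edges are kept for inspection. Genes in
#' several clusters appear in each of their subnetworks. Isolated
#' nodes are dropped, as in disease-network construction; a subnetwork
#' left with fewer than 3 nodes is kept but flagged, since its
#' centralization statistics are degenerate.
#'
#' @param assignments Data frame with columns `gene`, `cluster` (as
#'   from [load_clusters()]).
#' @param edges Cutoff-filtered PPI edge data frame (as from
#'   [load_ppi()]).
#' @param max_occurrence Maximum number of subnetworks an edge may
#'   appear in before it is removed from all of them (default 4:
#'   edges in more than four subnetworks are deleted).
#' @return An object of class `"subnetwork_set"`: list with
#'   `networks` (named list of igraph graphs, one per cluster),
#'   `edge_occurrence` (data frame edge -> count before pruning),
#'   `pruned_edges` (data frame of removed edges), `flagged`
#'   (clusters with < 3 surviving nodes), `max_occurrence`.
#' @export
build_subnetworks <- function(assignments, edges, max_occurrence = 4) {
  stopifnot(all(c("gene", "cluster") %in% names(assignments)))
  assignments$gene <- normalize_symbols(assignments$gene)
  clusters <- unique(assignments$cluster)
  if (length(clusters) == 0L) stop("no clusters in assignment table")

  lo <- pmin(edges$protein_a, edges$protein_b)
  hi <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(lo, hi, sep = "\t")

  # per-cluster logical edge masks
  masks <- lapply(clusters, function(cl) {
    genes <- assignments$gene[assignments$cluster == cl]
    lo %in% genes & hi %in% genes
  })
  names(masks) <- clusters

  occ_by_edge <- Reduce(`+`, lapply(masks, as.integer))
  over <- occ_by_edge > max_occurrence

  occurrence <- data.frame(protein_a = lo, protein_b = hi,
                           n_subnetworks = occ_by_edge,
                           stringsAsFactors = FALSE)
  occurrence <- occurrence[occurrence$n_subnetworks > 0L, , drop = FALSE]
  occurrence <- occurrence[order(occurrence$protein_a, occurrence$protein_b), ,
                           drop = FALSE]
  rownames(occurrence) <- NULL
  pruned <- unique(data.frame(protein_a = lo[over], protein_b = hi[over],
                              stringsAsFactors = FALSE))
  if (nrow(pruned) > 0L) {
    pruned <- pruned[order(pruned$protein_a, pruned$protein_b), , drop = FALSE]
    rownames(pruned) <- NULL
  }

  networks <- list()
  flagged <- character(0)
  for (cl in clusters) {
    keep <- masks[[cl]] & !over
    el <- data.frame(protein_a = lo[keep], protein_b = hi[keep],
                     stringsAsFactors = FALSE)
    if (nrow(el) == 0L) {
      g <- igraph::make_empty_graph(0, directed = FALSE)
    } else {
      g <- igraph::simplify(igraph::graph_from_data_frame(el, directed = FALSE))
    }
    if (igraph::vcount(g) < 3L) flagged <- c(flagged, cl)
    networks[[cl]] <- g
  }

  out <- list(networks = networks, edge_occurrence = occurrence,
              pruned_edges = pruned, flagged = flagged,
              max_occurrence = max_occurrence)
  class(out) <- "subnetwork_set"
  out
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat("Functional subnetworks (", length(x$networks),
      " cluster(s); edges in > ", x$max_occurrence,
      " subnetworks pruned: ", nrow(x$pruned_edges), ")\n", sep = "")
  for (cl in names(x$networks)) {
    g <- x$networks[[cl]]
    cat(sprintf("  %-25s %5d nodes %6d edges%s\n", cl,
                igraph::vcount(g), igraph::ecount(g),
                if (cl %in% x$flagged) "  [flagged: < 3 nodes]" else ""))
  }
  invisible(x)
}

#' Write subnetworks as edge-list TSVs
#'
#' One `<dir>/subnetwork_<cluster>.tsv` per cluster, plus
#' `<dir>/pruned_edges.tsv` with the interactions removed by the
#' shared-edge rule.
#'
#' @param subnets A `"subnetwork_set"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_subnetworks <- function(subnets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9._-]+", "_", names(subnets$networks))
  paths <- character(0)
  for (i in seq_along(subnets$networks)) {
    p <- file.path(dir, paste0("subnetwork_", safe[i], ".tsv"))
    write_network(subnets$networks[[i]], p)
    paths <- c(paths, p)
  }
  pp <- file.path(dir, "pruned_edges.tsv")
  utils::write.table(subnets$pruned_edges, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, pp))
}

#' Score drugs on every functional subnetwork
#'
#' Runs the attack-score pipeline for every (drug, subnetwork) pair.
#' Subnetworks too small to attack, or cells whose score is undefined,
#' appear as missing values with a recorded reason, never as 0.
#'
#' @param subnets A `"subnetwork_set"`.
#' @param drugs Named list of target-symbol vectors.
#' @inheritParams score_matrix
#' @return A `"score_matrix"` (drugs x subnetworks).
#' @export
score_subnetworks <- function(subnets, drugs, n_reps = 100, seed = 1L) {
  stopifnot(inherits(subnets, "subnetwork_set"))
  score_matrix(subnets$networks, drugs, n_reps = n_reps, seed = seed)
}
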