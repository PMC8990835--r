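# Whole-graph robustness statistics. All four are computed from
# unweighted shortest-path distances and vertex degrees; conventions for
# disconnected graphs are documented per function and in the package
# vignette.

# shared internals ----------------------------------------------------

# shortest-path distance matrix, all edges length 1
.dist_matrix <- function(net) {
  igraph::distances(net, algorithm = "unweighted")
}

# Wasserman-Faust component-scaled closeness from a distance matrix:
# clo(v) = ((n_C - 1)/(n - 1)) * ((n_C - 1) / sum_{t in C} d(v, t)).
# Reduces to (n-1)/sum d on a connected graph; isolated nodes get 0.
.closeness_wf <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(stats::setNames(0, rownames(D)))
  finite <- is.finite(D)
  diag(finite) <- FALSE
  reach <- rowSums(finite)                  # n_C - 1 for each vertex
  D[!finite] <- 0
  dsum <- rowSums(D)
  clo <- ifelse(reach > 0, (reach / (n - 1)) * (reach / dsum), 0)
  stats::setNames(clo, rownames(D))
}

.aspl_from_dist <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(NA_real_)
  finite <- is.finite(D)
  diag(finite) <- FALSE
  npairs <- sum(finite)
  if (npairs == 0L) {
    warning("no reachable pairs: average shortest path length undefined")
    return(NA_real_)
  }
  sum(D[finite]) / npairs
}

.dc_from_deg <- function(deg) {
  n <- length(deg)
  if (n < 3L) {
    warning("degree centralization undefined for n < 3; returning 0")
    return(0)
  }
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

.cc_from_clo <- function(clo) {
  n <- length(clo)
  if (n < 3L) {
    warning("closeness centralization undefined for n < 3; returning 0")
    return(0)
  }
  sum(max(clo) - clo) / ((n - 1) * (n - 2) / (2 * n - 3))
}

# user-facing operations ----------------------------------------------

#' Average degree of a network
#'
#' Mean number of edges incident to a node: `sum(deg(v)) / n`, which
#' equals `2 m / n`.
#'
#' @param net An igraph undirected graph with at least one node.
#' @return Average degree (non-negative real).
#' @export
average_degree <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1L) stop("average degree undefined on an empty network")
  2 * igraph::ecount(net) / n
}

#' Average shortest path length
#'
#' Mean of the shortest-path distance `d(s, t)` over all ordered pairs
#' of distinct, mutually reachable nodes. On a connected graph this is
#' the classical `sum d(s,t) / (n (n-1))`; on a disconnected graph
#' unreachable pairs are excluded from the average (a convention that
#' keeps the statistic finite after fragmenting attacks). A graph with
#' no reachable pair at all yields `NA` with a warning, never a silent
#' zero.
#'
#' @param net An igraph undirected graph with at least two nodes.
#' @return Mean shortest path length (>= 1 on any graph with an edge),
#'   or `NA_real_` if no pair is reachable.
#' @export
average_shortest_path_length <- function(net) {
  if (igraph::vcount(net) < 2L) {
    stop("average shortest path length needs at least 2 nodes")
  }
  .aspl_from_dist(.dist_matrix(net))
}

#' Degree centralization of a network
#'
#' Freeman whole-graph centralization of degree:
#' `sum_v [deg(v*) - deg(v)] / ((n-1)(n-2))`, where `v*` attains the
#' maximal degree. Equals 1 on a star and 0 on any vertex-transitive
#' graph. For `n < 3` the denominator vanishes; 0 is returned with a
#' warning so attacked subnetworks that shrink below 3 nodes still
#' yield a full profile.
#'
#' @param net An igraph undirected graph.
#' @return Centralization in `[0, 1]` on simple graphs.
#' @export
degree_centralization <- function(net) {
  .dc_from_deg(igraph::degree(net))
}

#' Closeness centralization of a network
#'
#' Freeman whole-graph centralization of closeness:
#' `sum_v [clo(v#) - clo(v)] / ((n-1)(n-2)/(2n-3))`, where `v#` attains
#' the maximal closeness and `clo(v) = (n-1) / sum_t d(v, t)` on a
#' connected graph. On disconnected graphs the Wasserman-Faust
#' component-scaled closeness is used (isolated nodes score 0), which
#' reduces to the classical value when the graph is connected. Equals 1
#' on a star, 0 on vertex-transitive graphs.
#'
#' @inheritParams degree_centralization
#' @return Centralization value.
#' @export
closeness_centralization <- function(net) {
  .cc_from_clo(.closeness_wf(.dist_matrix(net)))
}

#' Full topology profile of a network
#'
#' Computes the four whole-graph robustness statistics — average degree
#' (AD), average shortest path length (ASPL), degree centralization
#' (DC) and closeness centralization (CC) — together with node, edge
#' and component counts, from a single shortest-path distance pass.
#'
#' @param net An igraph undirected graph with at least one node.
#' @return An object of class `"topology_profile"`: a list with
#'   elements `ad`, `aspl`, `dc`, `cc`, `n_nodes`, `n_edges`,
#'   `n_components`.
#' @export
#' @examples
#' g <- igraph::make_full_graph(4)
#' topology_profile(g)
topology_profile <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1L) stop("topology profile undefined on an empty network")
  D <- .dist_matrix(net)
  deg <- igraph::degree(net)
  out <- list(
    ad = sum(deg) / n,
    aspl = if (n >= 2L) .aspl_from_dist(D) else NA_real_,
    dc = .dc_from_deg(deg),
    cc = .cc_from_clo(.closeness_wf(D)),
    n_nodes = n,
    n_edges = igraph::ecount(net),
    n_components = igraph::count_components(net)
  )
  class(out) <- "topology_profile"
  out
}

#' @export
print.topology_profile <- function(x, digits = 4, ...) {
  cat("Topology profile: ", x$n_nodes, " nodes, ", x$n_edges, " edges, ",
      x$n_components, " component(s)\n", sep = "")
  cat(sprintf("  AD   = %.*g\n  ASPL = %.*g\n  DC   = %.*g\n  CC   = %.*g\n",
              digits, x$ad, digits, x$aspl, digits, x$dc, digits, x$cc))
  invisible(x)
}

#' @export
as.data.frame.topology_profile <- function(x, ...) {
  data.frame(n_nodes = x$n_nodes, n_edges = x$n_edges,
             n_components = x$n_components,
             ad = x$ad, aspl = x$aspl, dc = x$dc, cc = x$cc)
}

#' Write topology profiles as a TSV
#'
#' One row per network with counts, the four statistics, and the
#' disconnected-graph conventions in force.
#'
#' @param profiles A named list of `"topology_profile"` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, as.data.frame))
  rows <- cbind(network_id = names(profiles), rows,
                conventions = "aspl=reachable-pairs; closeness=wasserman-faust")
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
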