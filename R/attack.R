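# Multi-target drug attack by node deletion, and the per-metric
# robustness index (relative change of each topology statistic).

#' Simulate a multi-target drug attack
#'
#' Deletes every network node that appears in the drug's target set,
#' together with all incident edges. Targets absent from the network
#' are ignored (target lists are typically far larger than any one
#' disease network) but the number of hits is reported. Surviving
#' nodes are retained even when the deletion isolates them, so the
#' after-attack node set is exactly the before set minus the hits.
#'
#' @param net An igraph undirected graph.
#' @param targets Character vector of target symbols (normalized
#'   internally).
#' @return An object of class `"attack_result"`: list with
#'   `attacked_network` (igraph), `hit_targets` (character), `n_hits`.
#' @export
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- c("A", "B", "C", "D")
#' attack(g, c("A", "B", "ZZZ"))
attack <- function(net, targets) {
  if (igraph::vcount(net) < 1L) stop("cannot attack an empty network")
  targets <- unique(normalize_symbols(targets))
  hits <- sort(intersect(targets, igraph::V(net)$name))
  if (length(hits) == igraph::vcount(net)) {
    stop("network annihilated: attack removes every node")
  }
  out <- list(
    attacked_network = igraph::delete_vertices(net, hits),
    hit_targets = hits,
    n_hits = length(hits)
  )
  class(out) <- "attack_result"
  out
}

#' @export
print.attack_result <- function(x, ...) {
  cat("Drug attack: ", x$n_hits, " target(s) hit; ",
      igraph::vcount(x$attacked_network), " nodes and ",
      igraph::ecount(x$attacked_network), " edges remain\n", sep = "")
  invisible(x)
}

#' Robustness index of an attack
#'
#' Relative change of each topology statistic,
#' `(after - before) / before`, computed for AD, ASPL, DC and CC. A
#' metric whose before-attack value is zero (or undefined) has an
#' undefined robustness index, reported as `NA` with a warning — never
#' silently coerced to 0.
#'
#' @param before Topology profile of the unattacked network.
#' @param after Topology profile of the attacked network.
#' @return An object of class `"robustness_index"`: list with
#'   `ri_ad`, `ri_aspl`, `ri_dc`, `ri_cc` and the two profiles.
#' @export
robustness_index <- function(before, after) {
  stopifnot(inherits(before, "topology_profile"),
            inherits(after, "topology_profile"))
  rel <- function(b, a, metric) {
    if (is.na(b) || is.na(a)) {
      warning("robustness index undefined for ", metric,
              ": metric undefined on ", if (is.na(b)) "before" else "after",
              " network")
      return(NA_real_)
    }
    if (b == 0) {
      warning("robustness index undefined for ", metric,
              ": before-attack value is 0")
      return(NA_real_)
    }
    (a - b) / b
  }
  out <- list(
    ri_ad = rel(before$ad, after$ad, "ad"),
    ri_aspl = rel(before$aspl, after$aspl, "aspl"),
    ri_dc = rel(before$dc, after$dc, "dc"),
    ri_cc = rel(before$cc, after$cc, "cc"),
    before = before,
    after = after
  )
  class(out) <- "robustness_index"
  out
}

#' @export
print.robustness_index <- function(x, digits = 4, ...) {
  cat("Robustness index (relative change after attack):\n")
  cat(sprintf("  RI_AD   = %.*g\n  RI_ASPL = %.*g\n  RI_DC   = %.*g\n  RI_CC   = %.*g\n",
              digits, x$ri_ad, digits, x$ri_aspl,
              digits, x$ri_dc, digits, x$ri_cc))
  invisible(x)
}

# numeric [ad, aspl, dc, cc] vector from a robustness_index
.ri_vec <- function(ri) {
  c(ad = ri$ri_ad, aspl = ri$ri_aspl, dc = ri$ri_dc, cc = ri$ri_cc)
}

# attack + before/after profiles + RI in one pass (quiet: callers in
# permutation loops count undefined draws rather than surfacing each
# warning)
.attack_ri <- function(net, targets, quiet = FALSE) {
  f <- if (quiet) suppressWarnings else identity
  res <- attack(net, targets)
  before <- f(topology_profile(net))
  after <- f(topology_profile(res$attacked_network))
  ri <- f(robustness_index(before, after))
  list(attack = res, ri = ri)
}
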