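# Random-network permutation null, z-score normalization of the
# robustness index, the composite total score, and the attack_score
# estimator that ties them together.

#' Random network with the same nodes and edge count
#'
#' Draws a uniform simple graph G(n, m) on the *same node label set* as
#' the input network (labels sorted, so the draw is independent of the
#' input's vertex order), with exactly the same number of edges. The
#' same drug attack can therefore be replayed on the random network,
#' since every target label still exists.
#'
#' @param net An igraph undirected graph.
#' @param seed Integer seed; the same seed always yields the same edge
#'   set.
#' @return An igraph undirected graph with `vcount(net)` nodes and
#'   `ecount(net)` edges.
#' @export
random_network <- function(net, seed) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  labels <- sort(igraph::V(net)$name)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  g <- igraph::sample_gnm(n, m, directed = FALSE)
  igraph::V(g)$name <- labels
  g
}

#' Null distribution of the robustness index
#'
#' Replays the same drug attack on `n_reps` random networks (uniform
#' G(n, m) draws preserving node labels and edge count) and collects
#' the per-metric robustness indices, their means and standard
#' deviations. The default of 100 replicates matches common practice
#' for this permutation test. Per-replicate seeds are `seed + i` for
#' replicate `i`, so the whole distribution is reproducible from the
#' master seed. Replicates where a metric is undefined (e.g. a
#' fragmented draw with a zero before-value) are excluded from that
#' metric's vector and counted in `n_excluded`.
#'
#' @param net The real network (its node/edge counts define the null).
#' @param targets Character vector of drug target symbols.
#' @param n_reps Number of random networks (>= 2).
#' @param seed Master integer seed.
#' @return An object of class `"null_distribution"`: list with `draws`
#'   (n_reps x 4 matrix, columns ad/aspl/dc/cc, NA for excluded),
#'   `mean`, `sd` (sample SD), `n_reps`, `n_excluded`, `seed`.
#' @export
null_distribution <- function(net, targets, n_reps = 100, seed = 1L) {
  stopifnot(n_reps >= 2)
  draws <- matrix(NA_real_, nrow = n_reps, ncol = 4,
                  dimnames = list(NULL, c("ad", "aspl", "dc", "cc")))
  for (i in seq_len(n_reps)) {
    rn <- random_network(net, seed + i)
    draws[i, ] <- .ri_vec(.attack_ri(rn, targets, quiet = TRUE)$ri)
  }
  n_def <- colSums(!is.na(draws))
  if (any(n_def < 2L)) {
    stop("fewer than 2 defined null draws for metric(s): ",
         paste(colnames(draws)[n_def < 2L], collapse = ", "))
  }
  out <- list(
    draws = draws,
    mean = colMeans(draws, na.rm = TRUE),
    sd = apply(draws, 2, stats::sd, na.rm = TRUE),
    n_reps = n_reps,
    n_excluded = n_reps - n_def,
    seed = as.integer(seed)
  )
  class(out) <- "null_distribution"
  out
}

#' @export
print.null_distribution <- function(x, digits = 4, ...) {
  cat("Permutation null (", x$n_reps, " random networks, seed ",
      x$seed, "):\n", sep = "")
  tab <- rbind(mean = x$mean, sd = x$sd, excluded = x$n_excluded)
  print(round(tab, digits))
  invisible(x)
}

#' Normalize a robustness index against its null distribution
#'
#' Per-metric z-score `(RI_real - mean_random) / sd_random`. A metric
#' whose null SD is zero (e.g. a drug with no hits, where every draw
#' gives RI 0) has an undefined z-score, returned as `NA` with a
#' warning rather than dividing by zero.
#'
#' @param ri A `"robustness_index"` for the real network.
#' @param null A `"null_distribution"` from the same attack.
#' @return An object of class `"normalized_ri"`: list with `z_ad`,
#'   `z_aspl`, `z_dc`, `z_cc`.
#' @export
normalized_ri <- function(ri, null) {
  stopifnot(inherits(ri, "robustness_index"),
            inherits(null, "null_distribution"))
  v <- .ri_vec(ri)
  z <- rep(NA_real_, 4L)
  names(z) <- names(v)
  for (k in seq_along(v)) {
    if (is.na(v[k])) {
      warning("normalized RI undefined for ", names(v)[k],
              ": real RI undefined")
    } else if (null$sd[k] == 0) {
      warning("normalized RI undefined for ", names(v)[k],
              ": null SD is 0")
    } else {
      z[k] <- (v[k] - null$mean[k]) / null$sd[k]
    }
  }
  out <- list(z_ad = z[["ad"]], z_aspl = z[["aspl"]],
              z_dc = z[["dc"]], z_cc = z[["cc"]])
  class(out) <- "normalized_ri"
  out
}

#' @export
print.normalized_ri <- function(x, digits = 4, ...) {
  cat(sprintf("Normalized RI (z-scores): AD %.*g, ASPL %.*g, DC %.*g, CC %.*g\n",
              digits, x$z_ad, digits, x$z_aspl,
              digits, x$z_dc, digits, x$z_cc))
  invisible(x)
}

#' Composite total attack score
#'
#' Combines the four normalized robustness indices as
#' `z_ASPL - z_AD - z_DC - z_CC`. A destabilizing attack lengthens
#' paths (positive ASPL change) and lowers degree and the two
#' centralizations (negative changes), so each term enters with the
#' sign that makes a larger total mean a more disruptive agent.
#'
#' @param nri A `"normalized_ri"` object, or a list/vector with
#'   elements `z_ad`, `z_aspl`, `z_dc`, `z_cc`.
#' @return The total score (real), or `NA` with a warning if any
#'   z-score is undefined.
#' @export
#' @examples
#' total_score(list(z_ad = -6.77, z_aspl = 7.01, z_dc = -0.16, z_cc = -11.88))
total_score <- function(nri) {
  z <- c(nri$z_ad, nri$z_aspl, nri$z_dc, nri$z_cc)
  if (length(z) != 4L) stop("need the four z-scores z_ad, z_aspl, z_dc, z_cc")
  if (any(is.na(z))) {
    warning("total score undefined: ",
            paste(c("z_ad", "z_aspl", "z_dc", "z_cc")[is.na(z)],
                  collapse = ", "), " undefined")
    return(NA_real_)
  }
  nri$z_aspl - nri$z_ad - nri$z_dc - nri$z_cc
}

#' Rank a score against a reference panel
#'
#' Percentage of reference scores that the score strictly exceeds
#' ("superior to" so many percent of the reference agents).
#'
#' @param score A total score.
#' @param reference_scores Non-empty numeric vector of reference
#'   scores (NAs dropped).
#' @return Percentage in `[0, 100]`.
#' @export
rank_against_reference <- function(score, reference_scores) {
  reference_scores <- reference_scores[!is.na(reference_scores)]
  if (length(reference_scores) == 0L) stop("empty reference score list")
  100 * sum(reference_scores < score) / length(reference_scores)
}

#' Score a drug attack on a network
#'
#' The central estimator of the package: attacks the network with the
#' drug's targets, computes the four-metric robustness index, builds
#' the random-network permutation null under the same attack,
#' normalizes each index to a z-score, and combines them into the
#' composite total score.
#'
#' @param net An igraph undirected disease network (named vertices).
#' @param targets Character vector of drug target symbols, or a named
#'   single-element list as produced by [load_targets()].
#' @param n_reps Number of random networks in the null (default 100).
#' @param seed Master integer seed for the permutation null.
#' @param drug_id,network_id Optional identifiers carried into the
#'   result.
#' @return An object of class `"attack_score"`: list with `drug_id`,
#'   `network_id`, `n_hits`, `hit_targets`, `ri`
#'   (`"robustness_index"`), `null` (`"null_distribution"`),
#'   `normalized` (`"normalized_ri"`), `total`, `n_reps`, `seed`.
#' @seealso [total_score()], [null_distribution()], [score_matrix()]
#' @export
#' @examples
#' set.seed(7)
#' g <- igraph::sample_gnm(30, 90)
#' igraph::V(g)$name <- sprintf("G%03d", 1:30)
#' fit <- attack_score(g, c("G001", "G002", "G003"), n_reps = 25, seed = 1)
#' fit
attack_score <- function(net, targets, n_reps = 100, seed = 1L,
                         drug_id = NULL, network_id = NULL) {
  if (is.list(targets)) {
    if (is.null(drug_id) && !is.null(names(targets))) drug_id <- names(targets)[1L]
    targets <- targets[[1L]]
  }
  real <- .attack_ri(net, targets, quiet = FALSE)
  null <- null_distribution(net, targets, n_reps = n_reps, seed = seed)
  nri <- normalized_ri(real$ri, null)
  out <- list(
    drug_id = drug_id,
    network_id = network_id,
    n_hits = real$attack$n_hits,
    hit_targets = real$attack$hit_targets,
    ri = real$ri,
    null = null,
    normalized = nri,
    total = suppressWarnings(total_score(nri)),
    n_reps = n_reps,
    seed = as.integer(seed)
  )
  class(out) <- "attack_score"
  out
}

#' @export
print.attack_score <- function(x, digits = 4, ...) {
  cat("Drug attack score",
      if (!is.null(x$drug_id)) paste0(" [", x$drug_id,
        if (!is.null(x$network_id)) paste0(" on ", x$network_id), "]"),
      "\n", sep = "")
  cat("  targets hit: ", x$n_hits, "; permutation null: ", x$n_reps,
      " random networks (seed ", x$seed, ")\n", sep = "")
  z <- x$normalized
  cat(sprintf("  z(AD) %.*g, z(ASPL) %.*g, z(DC) %.*g, z(CC) %.*g\n",
              digits, z$z_ad, digits, z$z_aspl,
              digits, z$z_dc, digits, z$z_cc))
  cat(sprintf("  total score = %.*g\n", digits, x$total))
  invisible(x)
}

#' @export
summary.attack_score <- function(object, ...) {
  b <- object$ri$before; a <- object$ri$after
  df <- data.frame(
    metric = c("ad", "aspl", "dc", "cc"),
    before = c(b$ad, b$aspl, b$dc, b$cc),
    after = c(a$ad, a$aspl, a$dc, a$cc),
    ri = unname(.ri_vec(object$ri)),
    null_mean = unname(object$null$mean),
    null_sd = unname(object$null$sd),
    z = c(object$normalized$z_ad, object$normalized$z_aspl,
          object$normalized$z_dc, object$normalized$z_cc)
  )
  out <- list(drug_id = object$drug_id, network_id = object$network_id,
              n_hits = object$n_hits, table = df, total = object$total)
  class(out) <- "summary.attack_score"
  out
}

#' @export
print.summary.attack_score <- function(x, digits = 4, ...) {
  cat("Attack score summary",
      if (!is.null(x$drug_id)) paste0(" [", x$drug_id, "]"), "\n", sep = "")
  cat("  targets hit:", x$n_hits, "\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("  total score = %.*g\n", digits, x$total))
  invisible(x)
}

#' Plot the permutation null with the observed robustness index
#'
#' One histogram per metric of the null robustness-index draws, with
#' the real network's RI marked; the visual analogue of the z-score.
#'
#' @param x An `"attack_score"` object.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.attack_score <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  v <- .ri_vec(x$ri)
  for (k in colnames(x$null$draws)) {
    d <- x$null$draws[, k]
    d <- d[!is.na(d)]
    graphics::hist(d, main = paste0("RI_", toupper(k)), xlab = "null RI",
                   xlim = range(c(d, v[k]), na.rm = TRUE), ...)
    graphics::abline(v = v[k], col = "red", lwd = 2)
  }
  invisible(x)
}

#' Score every (drug, network) pair
#'
#' Runs the full attack -> robustness index -> permutation null ->
#' z-score -> total-score pipeline for each drug on each network, with
#' a deterministic per-cell seed scheme: cell `k` (column-major over
#' drugs x networks) uses master seed `seed + (k - 1) * (n_reps + 1)`,
#' so every cell is independently reproducible.
#'
#' @param networks Named list of igraph networks.
#' @param drugs Named list of target-symbol vectors.
#' @param n_reps Null replicates per cell.
#' @param seed Master integer seed.
#' @return An object of class `"score_matrix"`: list with `total`
#'   (drugs x networks matrix, NA where undefined), `z` (4-slice
#'   array drugs x networks x metric), `n_hits` matrix, `reasons`
#'   (character matrix, "" where defined), `seeds` matrix, `n_reps`,
#'   `seed`.
#' @export
score_matrix <- function(networks, drugs, n_reps = 100, seed = 1L) {
  stopifnot(length(networks) > 0L, length(drugs) > 0L)
  if (is.null(names(networks))) names(networks) <- paste0("net", seq_along(networks))
  if (is.null(names(drugs))) names(drugs) <- paste0("drug", seq_along(drugs))
  nd <- length(drugs); nn <- length(networks)
  total <- matrix(NA_real_, nd, nn, dimnames = list(names(drugs), names(networks)))
  hits <- matrix(NA_integer_, nd, nn, dimnames = dimnames(total))
  reasons <- matrix("", nd, nn, dimnames = dimnames(total))
  seeds <- matrix(NA_integer_, nd, nn, dimnames = dimnames(total))
  z <- array(NA_real_, dim = c(nd, nn, 4),
             dimnames = c(dimnames(total), list(c("ad", "aspl", "dc", "cc"))))
  k <- 0L
  for (j in seq_len(nn)) {
    for (i in seq_len(nd)) {
      k <- k + 1L
      cell_seed <- as.integer(seed) + (k - 1L) * (n_reps + 1L)
      seeds[i, j] <- cell_seed
      fit <- tryCatch(
        withCallingHandlers(
          attack_score(networks[[j]], drugs[[i]], n_reps = n_reps,
                       seed = cell_seed, drug_id = names(drugs)[i],
                       network_id = names(networks)[j]),
          warning = function(w) {
            reasons[i, j] <<- paste0(reasons[i, j],
                                     if (nzchar(reasons[i, j])) "; ",
                                     conditionMessage(w))
            invokeRestart("muffleWarning")
          }),
        error = function(e) {
          reasons[i, j] <<- conditionMessage(e)
          NULL
        })
      if (!is.null(fit)) {
        total[i, j] <- fit$total
        hits[i, j] <- fit$n_hits
        z[i, j, ] <- c(fit$normalized$z_ad, fit$normalized$z_aspl,
                       fit$normalized$z_dc, fit$normalized$z_cc)
      }
    }
  }
  out <- list(total = total, z = z, n_hits = hits, reasons = reasons,
              seeds = seeds, n_reps = n_reps, seed = as.integer(seed))
  class(out) <- "score_matrix"
  out
}

#' @export
print.score_matrix <- function(x, digits = 4, ...) {
  cat("Attack score matrix (", nrow(x$total), " drug(s) x ",
      ncol(x$total), " network(s); ", x$n_reps,
      " null replicates per cell, master seed ", x$seed, ")\n", sep = "")
  print(round(x$total, digits))
  invisible(x)
}

#' Write a score matrix and its z-score companion as TSVs
#'
#' `<stem>_total.tsv` holds the composite scores (rows = drugs,
#' columns = networks; undefined cells empty, with a reason column in
#' the companion long table `<stem>_cells.tsv`, which also carries the
#' four z-scores, hit counts and per-cell seeds).
#'
#' @param x A `"score_matrix"`.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_score_matrix <- function(x, stem) {
  p1 <- paste0(stem, "_total.tsv")
  tot <- cbind(drug_id = rownames(x$total), as.data.frame(x$total))
  utils::write.table(tot, p1, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  p2 <- paste0(stem, "_cells.tsv")
  long <- expand.grid(drug_id = rownames(x$total),
                      network_id = colnames(x$total),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$n_hits <- as.vector(x$n_hits)
  long$z_ad <- as.vector(x$z[, , "ad"])
  long$z_aspl <- as.vector(x$z[, , "aspl"])
  long$z_dc <- as.vector(x$z[, , "dc"])
  long$z_cc <- as.vector(x$z[, , "cc"])
  long$total <- as.vector(x$total)
  long$seed <- as.vector(x$seeds)
  long$reason <- as.vector(x$reasons)
  utils::write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(c(p1, p2))
}
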