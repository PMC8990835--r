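# Peak-area-ratio aggregation: a chromatographic peak area ratio is a
# proxy for a compound's relative content; summing it over the
# compounds hitting a target, or hitting any target of a pathological
# process, weights targets and processes by available compound mass.

#' Read a compound table
#'
#' CSV with columns `compound`, `peak_area_ratio` (percent) and
#' `targets` (semicolon-separated symbols; may be empty).
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `compound`, `peak_area_ratio`, and
#'   list-column `targets` of normalized symbol vectors.
#' @export
load_compounds <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound", "peak_area_ratio", "targets")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("compound table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  par <- suppressWarnings(as.numeric(tab$peak_area_ratio))
  if (any(is.na(par))) {
    stop("compound table ", path, ": unparseable peak_area_ratio in row ",
         which(is.na(par))[1L])
  }
  if (any(par < 0)) stop("negative peak_area_ratio in ", path)
  tg <- lapply(strsplit(as.character(tab$targets), ";", fixed = TRUE),
               function(v) {
                 v <- normalize_symbols(v)
                 sort(unique(v[nzchar(v)]))
               })
  data.frame(compound = as.character(tab$compound),
             peak_area_ratio = par,
             targets = I(tg),
             stringsAsFactors = FALSE)
}

#' Sum of peak area ratios over compounds hitting a target
#'
#' Every compound whose target set contains the target contributes its
#' full peak area ratio; a target hit by no compound sums to 0.
#'
#' @param compounds Compound data frame (see [load_compounds()]).
#' @param target A single target symbol.
#' @return Summed peak area ratio (percent).
#' @export
target_peak_sum <- function(compounds, target) {
  target <- normalize_symbols(target)
  hit <- vapply(compounds$targets, function(tg) target %in% tg, logical(1))
  sum(compounds$peak_area_ratio[hit])
}

#' Peak-area score of a pathological process
#'
#' Sums peak area ratios over compounds targeting at least one of the
#' process's targets, counting each compound once per process even
#' when it hits several process targets (the ratio proxies compound
#' content, so double counting would exceed the total). The per-target
#' sums are also returned, un-deduplicated.
#'
#' @param compounds Compound data frame (see [load_compounds()]).
#' @param process_targets Non-empty character vector of target symbols
#'   belonging to the process.
#' @param process Optional process label carried into the result.
#' @return An object of class `"process_score"`: list with `process`,
#'   `process_sum`, `target_sums` (named numeric), `n_compounds`
#'   (number of distinct contributing compounds).
#' @export
process_peak_sum <- function(compounds, process_targets, process = NULL) {
  process_targets <- unique(normalize_symbols(process_targets))
  process_targets <- process_targets[nzchar(process_targets)]
  if (length(process_targets) == 0L) stop("empty process target set")
  hit <- vapply(compounds$targets,
                function(tg) any(process_targets %in% tg), logical(1))
  target_sums <- vapply(process_targets,
                        function(t) target_peak_sum(compounds, t),
                        numeric(1))
  out <- list(process = process,
              process_sum = sum(compounds$peak_area_ratio[hit]),
              target_sums = target_sums,
              n_compounds = sum(hit))
  class(out) <- "process_score"
  out
}

#' @export
print.process_score <- function(x, digits = 4, ...) {
  cat("Process peak-area score",
      if (!is.null(x$process)) paste0(" [", x$process, "]"), ":\n", sep = "")
  cat(sprintf("  %d compound(s), process sum = %.*g%%\n",
              x$n_compounds, digits, x$process_sum))
  invisible(x)
}

#' Score several pathological processes and write a tidy table
#'
#' @param compounds Compound data frame.
#' @param processes Named list of target-symbol vectors, one per
#'   process.
#' @param path Optional output TSV path; when given, a tidy table of
#'   (process, target, target_sum) rows plus one `TOTAL` row per
#'   process is written.
#' @return Named list of `"process_score"` objects, invisibly when
#'   `path` is given.
#' @export
score_processes <- function(compounds, processes, path = NULL) {
  stopifnot(length(processes) > 0L, !is.null(names(processes)))
  scores <- lapply(names(processes), function(p) {
    process_peak_sum(compounds, processes[[p]], process = p)
  })
  names(scores) <- names(processes)
  if (!is.null(path)) {
    rows <- do.call(rbind, lapply(scores, function(s) {
      rbind(data.frame(process = s$process, target = names(s$target_sums),
                       peak_area_sum = unname(s$target_sums)),
            data.frame(process = s$process, target = "TOTAL",
                       peak_area_sum = s$process_sum))
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(scores))
  }
  scores
}
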