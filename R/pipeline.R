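# End-to-end orchestration: assemble -> subnetworks -> attacks ->
# permutation scores -> rankings -> compound scores, from one flat
# key-value config, with every default and seed echoed into a JSON run
# manifest so any number in the output bundle can be reproduced.

.pipeline_defaults <- list(
  gda_cutoff = 0.01,
  ppi_cutoff = 0.4,
  max_edge_occurrence = 4,
  n_reps = 100,
  seed = 1L,
  disease_id = NULL,
  reference_drugs = NULL
)

#' Read a pipeline configuration
#'
#' A flat key-value YAML document. Recognized keys: input paths
#' (`gda`, `ppi`, `targets`, `clusters`, `compounds`), parameters
#' (`gda_cutoff` 0.01, `ppi_cutoff` 0.4, `max_edge_occurrence` 4,
#' `n_reps` 100, `seed`), `disease_id`, `reference_drugs` (drug ids
#' forming the reference panel for percent-superior ranking), and
#' `out` (output directory). Unset parameters take the defaults above.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return Named list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else as.list(path)
  for (k in names(.pipeline_defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- .pipeline_defaults[[k]]
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full drug-attack analysis
#'
#' Assembles the disease network from the configured GDA and PPI
#' tables, builds functional subnetworks from the cluster table,
#' scores every drug on the disease network and on every subnetwork
#' (attack -> robustness index -> permutation null -> z-scores ->
#' total score), ranks each drug's scores against the reference panel,
#' aggregates compound peak-area ratios per pathological process when
#' a compound table is configured, and writes the whole bundle plus a
#' JSON manifest. Identical config and seed produce a byte-identical
#' bundle.
#'
#' @param config Config list or YAML path (see [read_run_config()]).
#' @param out Output directory (overrides the config's `out`).
#' @return Invisibly, a list with the assembled objects: `network`,
#'   `subnetworks`, `disease_scores`, `subnet_scores`, `rankings`,
#'   `process_scores`, `manifest`.
#' @export
run_pipeline <- function(config, out = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out)) cfg$out <- out
  if (is.null(cfg$out)) stop("config must name an output directory ('out')")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)

  genes <- .stage("load_gda",
    load_gda(cfg$gda, score_cutoff = cfg$gda_cutoff,
             disease_id = cfg$disease_id))
  edges <- .stage("load_ppi",
    withCallingHandlers(
      load_ppi(cfg$ppi, confidence_cutoff = cfg$ppi_cutoff),
      warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
  net <- .stage("build_network", build_network(genes, edges))
  drugs <- .stage("load_targets", load_targets(cfg$targets))

  write_network(net, file.path(cfg$out, "network.tsv"))
  profile <- suppressWarnings(topology_profile(net))
  write_profiles(list(disease = profile), file.path(cfg$out, "profile.tsv"))

  subnets <- NULL
  subnet_scores <- NULL
  if (!is.null(cfg$clusters)) {
    assignments <- .stage("load_clusters", load_clusters(cfg$clusters))
    subnets <- .stage("build_subnetworks",
      build_subnetworks(assignments, edges,
                        max_occurrence = cfg$max_edge_occurrence))
    write_subnetworks(subnets, file.path(cfg$out, "subnetworks"))
  }

  disease_scores <- .stage("score_disease_network",
    score_matrix(list(disease = net), drugs,
                 n_reps = cfg$n_reps, seed = cfg$seed))
  write_score_matrix(disease_scores, file.path(cfg$out, "disease_scores"))

  # subnetwork cells continue the seed counter where disease cells stop
  subnet_seed <- as.integer(cfg$seed) +
    length(drugs) * (cfg$n_reps + 1L)
  if (!is.null(subnets)) {
    subnet_scores <- .stage("score_subnetworks",
      score_subnetworks(subnets, drugs,
                        n_reps = cfg$n_reps, seed = subnet_seed))
    write_score_matrix(subnet_scores, file.path(cfg$out, "subnetwork_scores"))
  }

  rankings <- NULL
  if (!is.null(cfg$reference_drugs)) {
    ref <- intersect(cfg$reference_drugs, rownames(disease_scores$total))
    if (length(ref) == 0L) stop("no reference drugs found in target table")
    mats <- list(disease = disease_scores$total)
    if (!is.null(subnet_scores)) mats <- c(mats, list(subnet_scores$total))
    rows <- list()
    for (m in mats) {
      for (col in colnames(m)) {
        for (d in rownames(m)) {
          panel <- m[setdiff(ref, d), col]
          panel <- panel[!is.na(panel)]
          pct <- if (is.na(m[d, col]) || length(panel) == 0L) NA_real_ else
            rank_against_reference(m[d, col], panel)
          rows[[length(rows) + 1L]] <- data.frame(
            drug_id = d, network_id = col, total = m[d, col],
            pct_superior = pct, stringsAsFactors = FALSE)
        }
      }
    }
    rankings <- do.call(rbind, rows)
    utils::write.table(rankings, file.path(cfg$out, "rankings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  process_scores <- NULL
  if (!is.null(cfg$compounds)) {
    compounds <- .stage("load_compounds", load_compounds(cfg$compounds))
    if (!is.null(subnets)) {
      processes <- lapply(subnets$networks, function(g) igraph::V(g)$name)
      process_scores <- .stage("score_processes",
        score_processes(compounds, processes,
                        path = file.path(cfg$out, "process_scores.tsv")))
    }
  }

  manifest <- list(
    package = "netattack",
    version = as.character(utils::packageVersion("netattack")),
    config = cfg[setdiff(names(cfg), "out")],
    seed = cfg$seed,
    subnetwork_seed = subnet_seed,
    n_reps = cfg$n_reps,
    conventions = list(
      gda_cutoff = "score strictly greater than cutoff",
      ppi_cutoff = "confidence strictly greater than cutoff",
      aspl = "mean over reachable ordered pairs",
      closeness = "Wasserman-Faust component-scaled",
      null_model = "uniform G(n,m), node labels preserved",
      null_sd = "sample standard deviation",
      ranking = "strictly-greater percent superior",
      components = "all non-isolated nodes retained"
    ),
    network = list(n_nodes = igraph::vcount(net),
                   n_edges = igraph::ecount(net)),
    subnetworks = if (!is.null(subnets)) {
      stats::setNames(lapply(subnets$networks, function(g)
        list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))),
        names(subnets$networks))
    },
    undefined_z_cells = list(
      disease = sum(is.na(disease_scores$z)),
      subnetworks = if (!is.null(subnet_scores)) sum(is.na(subnet_scores$z))
    ),
    warnings = warn_log
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(network = net, subnetworks = subnets,
                 disease_scores = disease_scores,
                 subnet_scores = subnet_scores,
                 rankings = rankings, process_scores = process_scores,
                 manifest = manifest))
}
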