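# Synthetic study system: planted-partition disease networks with
# known functional modules, drug target sets with tunable module
# specificity and hub bias, and compound tables. Everything a real run
# would download (association scores, PPI confidences, cluster
# memberships) is emulated in the exact file dialects the readers
# consume, with scores straddling the standard cutoffs so the filters
# are exercised.

.default_module_labels <- c("oxidative_stress", "inflammation",
                            "angiogenesis", "blood_coagulation",
                            "extracellular_matrix", "neuron_death")

#' Specification of a synthetic disease network
#'
#' Planted-partition (stochastic block model) parameters. The defaults
#' emulate a disease network of the scale seen in retinal-disease PPI
#' studies: ~600 genes in 6 functional modules with ~4500 expected
#' edges (within-module edge probability 0.12, between-module
#' 0.00624).
#'
#' @param n_genes Number of genes.
#' @param n_modules Number of planted modules.
#' @param p_within Within-module edge probability.
#' @param p_between Between-module edge probability
#'   (`p_between <= p_within`).
#' @param module_sizes Optional integer vector summing to `n_genes`;
#'   defaults to an (almost) equal split.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 600, n_modules = 6,
                           p_within = 0.12, p_between = 0.00624,
                           module_sizes = NULL, seed = 1L) {
  stopifnot(n_genes >= 2, n_modules >= 1,
            p_within >= 0, p_within <= 1,
            p_between >= 0, p_between <= 1)
  if (p_between > p_within) {
    stop("p_between must not exceed p_within (planted modules)")
  }
  if (is.null(module_sizes)) {
    base <- n_genes %/% n_modules
    module_sizes <- rep(base, n_modules)
    extra <- n_genes - sum(module_sizes)
    if (extra > 0) module_sizes[seq_len(extra)] <- module_sizes[seq_len(extra)] + 1L
  }
  if (sum(module_sizes) != n_genes) {
    stop("module sizes must sum to n_genes")
  }
  out <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              p_within = p_within, p_between = p_between,
              module_sizes = as.integer(module_sizes),
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' Expected edge count of a synthetic spec
#'
#' `sum_k C(size_k, 2) * p_within + n_between_pairs * p_between`.
#'
#' @param spec A `"synthetic_spec"`.
#' @return Expected number of edges (real).
#' @export
expected_edges <- function(spec) {
  within_pairs <- sum(choose(spec$module_sizes, 2))
  between_pairs <- choose(spec$n_genes, 2) - within_pairs
  within_pairs * spec$p_within + between_pairs * spec$p_between
}

#' Generate a synthetic disease network with planted modules
#'
#' Draws a planted-partition graph, labels genes `G000001...`, and
#' (optionally) writes the full set of input tables the assembly
#' readers consume: a gene-disease association TSV whose planted genes
#' score above the 0.01 cutoff and whose decoy genes score below it, a
#' PPI TSV whose planted edges have confidence above 0.4 and whose
#' decoy edges fall below, a gene-to-cluster TSV matching the planted
#' modules, and a JSON ground-truth manifest. Deterministic given the
#' spec's seed; re-running with the same spec produces byte-identical
#' files.
#'
#' @param spec A `"synthetic_spec"`.
#' @param dir Optional output directory; when `NULL` nothing is
#'   written.
#' @param disease_id Disease identifier written into the GDA table.
#' @param frac_decoy_genes Fraction of extra below-cutoff genes added
#'   to the GDA table.
#' @param frac_decoy_edges Fraction of extra below-cutoff interactions
#'   added to the PPI table.
#' @return List with `network` (igraph; isolated genes dropped, as the
#'   assembly step would), `assignments` (gene/cluster data frame over
#'   all planted genes), `spec`, `manifest` (list), and `files` (named
#'   character vector of written paths, or `NULL`).
#' @export
generate_disease_network <- function(spec, dir = NULL,
                                     disease_id = "SYN0000001",
                                     frac_decoy_genes = 0.05,
                                     frac_decoy_edges = 0.10) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (expected_edges(spec) > choose(spec$n_genes, 2)) {
    stop("infeasible spec: expected edges exceed simple-graph capacity")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  labels <- if (spec$n_modules <= length(.default_module_labels)) {
    .default_module_labels[seq_len(spec$n_modules)]
  } else {
    sprintf("module_%02d", seq_len(spec$n_modules))
  }
  genes <- sprintf("G%06d", seq_len(spec$n_genes))
  membership <- rep(labels, times = spec$module_sizes)

  pref <- matrix(spec$p_between, spec$n_modules, spec$n_modules)
  diag(pref) <- spec$p_within
  g <- igraph::sample_sbm(spec$n_genes, pref.matrix = pref,
                          block.sizes = spec$module_sizes, directed = FALSE)
  igraph::V(g)$name <- genes

  el <- igraph::as_edgelist(g)
  assignments <- data.frame(gene = genes, cluster = membership,
                            stringsAsFactors = FALSE)

  files <- NULL
  gda <- ppi <- NULL
  n_decoy_genes <- max(1L, round(frac_decoy_genes * spec$n_genes))
  n_decoy_edges <- max(1L, round(frac_decoy_edges * nrow(el)))
  decoy_genes <- sprintf("X%06d", seq_len(n_decoy_genes))
  gda <- data.frame(
    gene = c(genes, decoy_genes),
    disease_id = disease_id,
    score = c(stats::runif(spec$n_genes, 0.02, 0.95),
              stats::runif(n_decoy_genes, 0, 0.0099)),
    stringsAsFactors = FALSE)
  # decoy interactions: random gene pairs at sub-cutoff confidence
  d1 <- sample(genes, n_decoy_edges, replace = TRUE)
  d2 <- sample(genes, n_decoy_edges, replace = TRUE)
  ok <- d1 != d2
  ppi <- data.frame(
    protein1 = c(el[, 1L], d1[ok]),
    protein2 = c(el[, 2L], d2[ok]),
    combined_score = c(stats::runif(nrow(el), 0.401, 0.999),
                       stats::runif(sum(ok), 0.05, 0.399)),
    stringsAsFactors = FALSE)

  # network as assembly would build it: isolated planted genes dropped
  deg <- igraph::degree(g)
  net <- igraph::delete_vertices(g, which(deg == 0))
  igraph::graph_attr(net, "conventions") <-
    "all non-isolated nodes retained (not restricted to largest component)"

  manifest <- list(
    generator = "planted-partition (stochastic block model)",
    seed = spec$seed,
    n_genes = spec$n_genes,
    n_modules = spec$n_modules,
    module_labels = labels,
    module_sizes = spec$module_sizes,
    p_within = spec$p_within,
    p_between = spec$p_between,
    expected_edges = expected_edges(spec),
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    n_isolated_dropped = sum(deg == 0),
    membership = stats::setNames(as.list(membership), genes)
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(gda = file.path(dir, "gda.tsv"),
               ppi = file.path(dir, "ppi.tsv"),
               clusters = file.path(dir, "clusters.tsv"),
               manifest = file.path(dir, "ground_truth.json"))
    utils::write.table(gda, files[["gda"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ppi, files[["ppi"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(assignments, files[["clusters"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  list(network = net, assignments = assignments, spec = spec,
       gda = gda, ppi = ppi, manifest = manifest, files = files)
}

#' Specification of a synthetic drug
#'
#' @param drug_id Identifier string.
#' @param n_targets Number of targets to sample.
#' @param focus_module Module label the drug concentrates on, or
#'   `NULL` for an unfocused drug.
#' @param specificity Fraction of targets drawn from the focus module
#'   (in `[0, 1]`; 0 means uniform targeting over all genes).
#' @param hub_bias Degree-proportional sampling exponent (>= 0):
#'   sampling weight `deg(v)^hub_bias`, so 0 is uniform and larger
#'   values concentrate targets on hubs.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_drug_spec"`.
#' @export
synthetic_drug_spec <- function(drug_id, n_targets, focus_module = NULL,
                                specificity = 0, hub_bias = 0, seed = 1L) {
  stopifnot(n_targets >= 1, specificity >= 0, specificity <= 1,
            hub_bias >= 0)
  if (specificity > 0 && is.null(focus_module)) {
    stop("specificity > 0 requires a focus_module")
  }
  out <- list(drug_id = as.character(drug_id),
              n_targets = as.integer(n_targets),
              focus_module = focus_module,
              specificity = specificity, hub_bias = hub_bias,
              seed = as.integer(seed))
  class(out) <- "synthetic_drug_spec"
  out
}

#' Sample a synthetic drug target set
#'
#' Draws `round(specificity * n_targets)` targets from the focus
#' module and the remainder from the other genes, each without
#' replacement with sampling weight `deg(v)^hub_bias`.
#'
#' @param dspec A `"synthetic_drug_spec"`.
#' @param net The disease network the drug will attack (named
#'   vertices).
#' @param modules Gene/cluster assignment data frame.
#' @return Sorted character vector of target symbols.
#' @export
generate_drug <- function(dspec, net, modules) {
  stopifnot(inherits(dspec, "synthetic_drug_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(dspec$seed)

  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  w <- if (dspec$hub_bias == 0) rep(1, length(nodes)) else deg^dspec$hub_bias
  names(w) <- nodes
  if (dspec$n_targets > length(nodes)) {
    stop("n_targets exceeds the number of available genes")
  }

  k_focus <- round(dspec$specificity * dspec$n_targets)
  focus_genes <- character(0)
  if (k_focus > 0) {
    focus_genes <- intersect(
      modules$gene[modules$cluster == dspec$focus_module], nodes)
    if (k_focus > length(focus_genes)) {
      stop("n_targets at this specificity exceeds focus module size")
    }
  }
  pick_focus <- if (k_focus > 0) {
    sample(focus_genes, k_focus, prob = w[focus_genes])
  } else character(0)
  rest_pool <- setdiff(nodes, pick_focus)
  k_rest <- dspec$n_targets - k_focus
  pick_rest <- if (k_rest > 0) {
    sample(rest_pool, k_rest, prob = w[rest_pool])
  } else character(0)
  sort(c(pick_focus, pick_rest))
}

#' Generate a synthetic compound table
#'
#' Compounds with log-normal peak area ratios rescaled to sum to
#' `total_percent`, and random target sets drawn from a pool.
#'
#' @param n_compounds Number of compounds.
#' @param target_pool Character vector of candidate target symbols.
#' @param mean_targets Mean target-set size (Poisson; zero-target
#'   compounds allowed).
#' @param total_percent Sum of all peak area ratios.
#' @param seed Integer seed.
#' @param path Optional CSV output path (dialect of
#'   [load_compounds()]).
#' @return Compound data frame (see [load_compounds()]).
#' @export
generate_compounds <- function(n_compounds = 20, target_pool,
                               mean_targets = 3, total_percent = 60,
                               seed = 1L, path = NULL) {
  stopifnot(n_compounds >= 1, length(target_pool) >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  raw <- stats::rlnorm(n_compounds, meanlog = 0, sdlog = 1)
  ratio <- round(total_percent * raw / sum(raw), 4)
  sizes <- pmin(stats::rpois(n_compounds, mean_targets), length(target_pool))
  tg <- lapply(sizes, function(k) sort(sample(target_pool, k)))
  tab <- data.frame(compound = sprintf("CMP%03d", seq_len(n_compounds)),
                    peak_area_ratio = ratio,
                    targets = I(tg),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    flat <- data.frame(compound = tab$compound,
                       peak_area_ratio = tab$peak_area_ratio,
                       targets = vapply(tab$targets, paste,
                                        character(1), collapse = ";"))
    utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  }
  tab
}
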