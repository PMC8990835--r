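# Synthetic planted-module disease networks, drugs and files.

test_that("the default spec targets the disease-network scale", {
  spec <- synthetic_spec()
  expect_equal(spec$n_genes, 600L)
  expect_equal(spec$n_modules, 6L)
  # expected edge count from the planted-partition formula
  within_pairs <- sum(choose(spec$module_sizes, 2))
  between_pairs <- choose(600, 2) - within_pairs
  manual <- within_pairs * spec$p_within + between_pairs * spec$p_between
  expect_equal(expected_edges(spec), manual)
  expect_lt(abs(expected_edges(spec) - 4500) / 4500, 0.10)
})

test_that("spec validation catches inconsistent inputs", {
  expect_error(synthetic_spec(p_within = 0.1, p_between = 0.2), "p_between")
  expect_error(synthetic_spec(n_genes = 10, module_sizes = c(3, 3)), "sum")
  # equal probabilities are allowed: the no-module null construction
  expect_s3_class(synthetic_spec(p_within = 0.1, p_between = 0.1),
                  "synthetic_spec")
})

test_that("realized edge counts track the expectation", {
  spec <- synthetic_spec(seed = 77)
  sim <- generate_disease_network(spec)
  expect_lt(abs(igraph::ecount(sim$network) - expected_edges(spec)) /
              expected_edges(spec), 0.10)
  expect_equal(sort(unique(sim$assignments$cluster)),
               sort(unique(unlist(sim$manifest$membership))))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_genes = 80, n_modules = 3, p_within = 0.3,
                         p_between = 0.04, seed = 13)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  s1 <- generate_disease_network(spec, dir = d1)
  s2 <- generate_disease_network(spec, dir = d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
})

test_that("generated tables round-trip through the assembly readers", {
  spec <- synthetic_spec(n_genes = 80, n_modules = 3, p_within = 0.3,
                         p_between = 0.04, seed = 29)
  dir <- tempfile()
  sim <- generate_disease_network(spec, dir = dir)
  expect_no_warning(genes <- load_gda(sim$files[["gda"]], 0.01))
  expect_no_warning(edges <- load_ppi(sim$files[["ppi"]], 0.4))
  net <- build_network(genes, edges)
  # decoy genes and sub-cutoff interactions are filtered back out,
  # leaving exactly the planted graph (minus isolated genes)
  expect_setequal(igraph::V(net)$name, igraph::V(sim$network)$name)
  canon <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(canon(net), canon(sim$network))
  clusters <- load_clusters(sim$files[["clusters"]])
  expect_setequal(clusters$cluster, unique(sim$assignments$cluster))
})

test_that("fully specific drugs target only their focus module", {
  spec <- synthetic_spec(n_genes = 90, n_modules = 3, p_within = 0.3,
                         p_between = 0.04, seed = 31)
  sim <- generate_disease_network(spec)
  label <- sim$assignments$cluster[1]
  ds <- synthetic_drug_spec("d1", n_targets = 10, focus_module = label,
                            specificity = 1, hub_bias = 0, seed = 3)
  tg <- generate_drug(ds, sim$network, sim$assignments)
  expect_length(tg, 10)
  mods <- sim$assignments$cluster[match(tg, sim$assignments$gene)]
  expect_true(all(mods == label))
  # identical seed, identical draw
  expect_identical(tg, generate_drug(ds, sim$network, sim$assignments))
  # asking for more module targets than the module holds is an error
  too_big <- synthetic_drug_spec("d2", n_targets = 60, focus_module = label,
                                 specificity = 1, seed = 3)
  expect_error(generate_drug(too_big, sim$network, sim$assignments),
               "module size")
})

test_that("unfocused drugs overlap modules at the hypergeometric rate", {
  spec <- synthetic_spec(n_genes = 120, n_modules = 3, p_within = 0.25,
                         p_between = 0.04, seed = 37)
  sim <- generate_disease_network(spec)
  nodes <- igraph::V(sim$network)$name
  label <- sim$assignments$cluster[1]
  K <- sum(sim$assignments$gene[sim$assignments$cluster == label] %in% nodes)
  N <- length(nodes); t <- 12
  overlaps <- vapply(1:200, function(s) {
    ds <- synthetic_drug_spec("u", n_targets = t, specificity = 0,
                              hub_bias = 0, seed = s)
    tg <- generate_drug(ds, sim$network, sim$assignments)
    sum(tg %in% sim$assignments$gene[sim$assignments$cluster == label])
  }, numeric(1))
  mu <- t * K / N
  sd1 <- sqrt(t * (K / N) * (1 - K / N) * (N - t) / (N - 1))
  expect_lt(abs(mean(overlaps) - mu), 4 * sd1 / sqrt(200))
})

test_that("hub bias concentrates targets on high-degree genes", {
  spec <- synthetic_spec(n_genes = 100, n_modules = 2, p_within = 0.25,
                         p_between = 0.05, seed = 43)
  sim <- generate_disease_network(spec)
  deg <- igraph::degree(sim$network)
  mean_deg <- mean(deg)
  target_degs <- vapply(1:50, function(s) {
    ds <- synthetic_drug_spec("h", n_targets = 10, specificity = 0,
                              hub_bias = 3, seed = 100 + s)
    mean(deg[generate_drug(ds, sim$network, sim$assignments)])
  }, numeric(1))
  expect_gt(mean(target_degs), mean_deg)
})
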