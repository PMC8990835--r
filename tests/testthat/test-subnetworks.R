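# Functional subnetworks: induced subgraphs per cluster and the
# shared-edge pruning rule.

# six clusters all containing genes A and B (edge A-B appears in the
# induced subgraph of every cluster it belongs to), plus a private
# edge per cluster
six_cluster_fixture <- function(n_shared = 5) {
  clusters <- paste0("c", 1:6)
  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    if (i <= n_shared) rows[[length(rows) + 1L]] <-
      data.frame(gene = c("A", "B"), cluster = cl)
    rows[[length(rows) + 1L]] <-
      data.frame(gene = c(paste0("P", i), paste0("Q", i)), cluster = cl)
  }
  assignments <- do.call(rbind, rows)
  edges <- data.frame(
    protein_a = c("A", paste0("P", 1:6)),
    protein_b = c("B", paste0("Q", 1:6)),
    confidence = 0.9)
  list(assignments = assignments, edges = edges)
}

test_that("an edge in more than four subnetworks is removed from all", {
  fx <- six_cluster_fixture(n_shared = 5)
  sn <- build_subnetworks(fx$assignments, fx$edges, max_occurrence = 4)
  # A-B occurred in 5 subnetworks: gone everywhere, recorded as pruned
  for (cl in names(sn$networks)) {
    e <- igraph::as_edgelist(sn$networks[[cl]])
    expect_false(any(e[, 1] == "A" & e[, 2] == "B" |
                     e[, 1] == "B" & e[, 2] == "A"))
  }
  expect_equal(nrow(sn$pruned_edges), 1)
  expect_equal(sn$pruned_edges$protein_a, "A")
  occ <- sn$edge_occurrence
  expect_equal(occ$n_subnetworks[occ$protein_a == "A" & occ$protein_b == "B"], 5)
})

test_that("an edge in exactly four subnetworks is retained everywhere", {
  fx <- six_cluster_fixture(n_shared = 4)
  sn <- build_subnetworks(fx$assignments, fx$edges, max_occurrence = 4)
  hits <- vapply(sn$networks[paste0("c", 1:4)], function(g) {
    e <- igraph::as_edgelist(g)
    any((e[, 1] == "A" & e[, 2] == "B") | (e[, 1] == "B" & e[, 2] == "A"))
  }, logical(1))
  expect_true(all(hits))  # boundary: "more than four", 4 is kept
  expect_equal(nrow(sn$pruned_edges), 0)
})

test_that("genes outside every cluster appear in no subnetwork", {
  fx <- six_cluster_fixture()
  fx$edges <- rbind(fx$edges,
                    data.frame(protein_a = "ORPHAN", protein_b = "A",
                               confidence = 0.9))
  sn <- build_subnetworks(fx$assignments, fx$edges)
  all_nodes <- unlist(lapply(sn$networks, function(g) igraph::V(g)$name))
  expect_false("ORPHAN" %in% all_nodes)
})

test_that("subnetwork nodes stay inside their cluster's genes", {
  fx <- six_cluster_fixture()
  sn <- build_subnetworks(fx$assignments, fx$edges)
  for (cl in names(sn$networks)) {
    genes <- fx$assignments$gene[fx$assignments$cluster == cl]
    expect_true(all(igraph::V(sn$networks[[cl]])$name %in% genes))
  }
})

test_that("tightening max_occurrence never grows a subnetwork", {
  fx <- six_cluster_fixture(n_shared = 5)
  prev <- NULL
  for (mo in c(6, 4, 2, 0)) {
    sn <- build_subnetworks(fx$assignments, fx$edges, max_occurrence = mo)
    sizes <- vapply(sn$networks, igraph::ecount, numeric(1))
    if (!is.null(prev)) expect_true(all(sizes <= prev[names(sizes)]))
    prev <- sizes
  }
})

test_that("tiny clusters are kept but flagged as degenerate", {
  assignments <- data.frame(gene = c("A", "B", "P1", "Q1", "R1"),
                            cluster = c("tiny", "tiny", "big", "big", "big"))
  edges <- data.frame(protein_a = c("A", "P1", "Q1"),
                      protein_b = c("B", "Q1", "R1"),
                      confidence = 0.9)
  sn <- build_subnetworks(assignments, edges)
  expect_true("tiny" %in% sn$flagged)
  expect_false("big" %in% sn$flagged)
  expect_equal(igraph::vcount(sn$networks$tiny), 2)
})

test_that("score_subnetworks scores every (drug, subnetwork) cell", {
  set.seed(81)
  # two clusters with enough structure to attack
  genes1 <- sprintf("A%02d", 1:12); genes2 <- sprintf("B%02d", 1:12)
  mk_edges <- function(genes, m) {
    pr <- t(combn(genes, 2))
    pr <- pr[sample(nrow(pr), m), , drop = FALSE]
    data.frame(protein_a = pmin(pr[, 1], pr[, 2]),
               protein_b = pmax(pr[, 1], pr[, 2]), confidence = 0.9)
  }
  assignments <- data.frame(gene = c(genes1, genes2),
                            cluster = rep(c("ox", "inf"), each = 12))
  edges <- rbind(mk_edges(genes1, 30), mk_edges(genes2, 30))
  sn <- build_subnetworks(assignments, edges)
  drugs <- list(dA = genes1[1:3], none = "ZZZ")
  sm <- score_subnetworks(sn, drugs, n_reps = 15, seed = 4)
  expect_equal(dim(sm$total), c(2, 2))
  expect_false(is.na(sm$total["dA", "ox"]))
  # no-hit drug: missing with reason, not zero
  expect_true(all(is.na(sm$total["none", ])))
  expect_true(all(nzchar(sm$reasons["none", ])))
})
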