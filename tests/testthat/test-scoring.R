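# Random-network null, z-score normalization, total score, ranking.

test_that("random_network preserves labels and counts, deterministically", {
  # n = 4, m = 6 forces the complete graph whatever the seed
  rk <- random_network(k4(), seed = 99)
  expect_equal(igraph::vcount(rk), 4)
  expect_equal(igraph::ecount(rk), 6)
  expect_setequal(igraph::V(rk)$name, c("A", "B", "C", "D"))

  iso <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(iso)$name <- letters[1:5]
  expect_equal(igraph::ecount(random_network(iso, 1)), 0)

  set.seed(71)
  g <- rand_named_gnp(20, 0.3)
  r1 <- random_network(g, 5); r2 <- random_network(g, 5)
  canon <- function(gg) {
    e <- igraph::as_edgelist(gg)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(canon(r1), canon(r2))
  expect_equal(igraph::ecount(r1), igraph::ecount(g))
  # the draw must not depend on the input's vertex order
  g_perm <- igraph::permute(g, sample(igraph::vcount(g)))
  expect_identical(canon(random_network(g_perm, 5)), canon(r1))
})

test_that("null_distribution is reproducible and handles no-hit drugs", {
  set.seed(41)
  g <- rand_named_gnp(15, 0.3)
  tg <- igraph::V(g)$name[1:3]
  n1 <- null_distribution(g, tg, n_reps = 20, seed = 7)
  n2 <- null_distribution(g, tg, n_reps = 20, seed = 7)
  expect_identical(n1$draws, n2$draws)
  expect_equal(nrow(n1$draws), 20)
  expect_true(all(n1$sd >= 0))

  # a drug that hits nothing leaves every random network unchanged
  n0 <- null_distribution(g, c("NOPE1", "NOPE2"), n_reps = 10, seed = 1)
  expect_equal(unname(n0$mean), c(0, 0, 0, 0))
  expect_equal(unname(n0$sd), c(0, 0, 0, 0))
})

test_that("null_distribution errors name the metric when draws vanish", {
  g <- named_graph(rbind(c("A", "B")))  # n = 2: dc/cc degenerate -> RI undefined
  expect_error(null_distribution(g, "A", n_reps = 5, seed = 1),
               "dc")
})

test_that("null means agree with a large brute-force re-estimate", {
  # 10-node, 20-edge fixture attacked on 3 fixed labels; the production
  # 100-rep null is compared with an independent 10,000-rep Monte-Carlo
  # oracle (own G(n,m) sampler, Floyd-Warshall statistics)
  set.seed(123)
  g <- igraph::sample_gnm(10, 20)
  igraph::V(g)$name <- sprintf("N%02d", 1:10)
  labels <- sort(igraph::V(g)$name)
  tg <- c("N01", "N04", "N07")

  null <- null_distribution(g, tg, n_reps = 100, seed = 10)

  set.seed(202)
  reps <- 10000
  draws <- matrix(NA_real_, reps, 4)
  for (i in seq_len(reps)) {
    draws[i, ] <- oracle_ri(labels, oracle_gnm_edges(labels, 20), tg)
  }
  for (k in 1:4) {
    d <- draws[, k]; d <- d[!is.na(d)]
    se <- sqrt(null$sd[k]^2 / sum(!is.na(null$draws[, k])) +
               stats::sd(d)^2 / length(d))
    expect_lt(abs(null$mean[k] - mean(d)), 3 * se)
  }
})

test_that("normalized_ri is the guarded z-score", {
  fake_ri <- structure(list(ri_ad = 0.2, ri_aspl = 0.2, ri_dc = 0.1,
                            ri_cc = NA_real_),
                       class = "robustness_index")
  fake_null <- structure(list(
    mean = c(ad = 0.1, aspl = 0.2, dc = 0.1, cc = 0),
    sd = c(ad = 0.05, aspl = 0.1, dc = 0, cc = 0.1)),
    class = "null_distribution")
  w <- capture_warnings(z <- normalized_ri(fake_ri, fake_null))
  expect_length(w, 2)              # dc (SD 0) and cc (undefined RI) flagged
  expect_match(w, "undefined", all = TRUE)
  expect_equal(z$z_ad, 2.0)      # (0.2 - 0.1)/0.05
  expect_equal(z$z_aspl, 0.0)    # equals the null mean
  expect_true(is.na(z$z_dc))     # null SD 0: flagged, not divided
  expect_true(is.na(z$z_cc))     # real RI undefined propagates
})

test_that("total score combines z-scores with the documented signs", {
  expect_equal(total_score(list(z_ad = 0, z_aspl = 0, z_dc = 0, z_cc = 0)), 0)
  base <- list(z_ad = 0.3, z_aspl = -1.2, z_dc = 2.0, z_cc = -0.7)
  t0 <- total_score(base)
  d <- 0.37
  for (slot in c("z_aspl", "z_ad", "z_dc", "z_cc")) {
    pert <- base
    pert[[slot]] <- pert[[slot]] + d
    expect_equal(total_score(pert) - t0, if (slot == "z_aspl") d else -d)
  }
  expect_warning(v <- total_score(list(z_ad = NA, z_aspl = 1, z_dc = 0,
                                       z_cc = 0)), "undefined")
  expect_true(is.na(v))
})

test_that("percent-superior ranking uses strict inequality", {
  expect_equal(rank_against_reference(5, c(1, 2, 3)), 100)
  expect_equal(rank_against_reference(5, c(6, 7)), 0)
  expect_equal(rank_against_reference(5, c(5, 4)), 50)  # tie does not count
  expect_error(rank_against_reference(5, numeric(0)), "empty")
})

test_that("attack_score ties the stages together reproducibly", {
  set.seed(51)
  g <- igraph::sample_gnm(30, 90)
  igraph::V(g)$name <- sprintf("G%03d", 1:30)
  tg <- c("G001", "G002", "G003", "G004")
  f1 <- attack_score(g, tg, n_reps = 30, seed = 3, drug_id = "d1")
  f2 <- attack_score(g, tg, n_reps = 30, seed = 3, drug_id = "d1")
  expect_identical(f1$total, f2$total)
  expect_equal(f1$n_hits, 4)
  expect_equal(f1$total,
               f1$normalized$z_aspl - f1$normalized$z_ad -
                 f1$normalized$z_dc - f1$normalized$z_cc)
  s <- summary(f1)
  expect_s3_class(s, "summary.attack_score")
  expect_equal(nrow(s$table), 4)
})

test_that("score_matrix is deterministic with recorded per-cell seeds", {
  set.seed(61)
  g1 <- igraph::sample_gnm(20, 50); igraph::V(g1)$name <- sprintf("A%03d", 1:20)
  g2 <- igraph::sample_gnm(20, 55); igraph::V(g2)$name <- sprintf("A%03d", 1:20)
  drugs <- list(d1 = c("A001", "A002"), d2 = c("A003", "A004", "A005"),
                dz = c("ZZZ"))
  m1 <- score_matrix(list(n1 = g1, n2 = g2), drugs, n_reps = 15, seed = 2)
  m2 <- score_matrix(list(n1 = g1, n2 = g2), drugs, n_reps = 15, seed = 2)
  expect_identical(m1$total, m2$total)
  expect_equal(dim(m1$total), c(3, 2))
  # zero-hit drug: undefined with a recorded reason, never a number
  expect_true(is.na(m1$total["dz", "n1"]))
  expect_match(m1$reasons["dz", "n1"], "SD is 0")
  # each defined cell is reproducible from its recorded seed alone
  fit <- attack_score(g2, drugs$d2, n_reps = 15, seed = m1$seeds["d2", "n2"])
  expect_equal(fit$total, m1$total["d2", "n2"])
})
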