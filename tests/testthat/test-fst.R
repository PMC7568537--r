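# Differentiation statistics against independent component-formula oracles.

test_that("Weir-Cockerham theta handles fixed and identical populations", {
  fx <- make_pair_matrix(c(5, 0, 0), c(0, 0, 4))
  expect_equal(weir_cockerham_fst(fx$x, fx$pm, "A", "B")$theta, 1)
  same <- make_pair_matrix(c(5, 3, 2), c(5, 3, 2))
  expect_lte(weir_cockerham_fst(same$x, same$pm, "A", "B")$theta, 0)
})

test_that("Weir-Cockerham theta equals the component-formula oracle", {
  fx <- make_pair_matrix(c(5, 3, 2), c(1, 4, 5))
  got <- weir_cockerham_fst(fx$x, fx$pm, "A", "B")$theta
  expect_equal(got, wc_theta_oracle(c(5, 3, 2), c(1, 4, 5)), tolerance = 1e-12)

  set.seed(23)
  for (i in 1:25) {
    repeat {
      ca <- as.integer(rmultinom(1, sample(2:10, 1), runif(3, 0.05, 1)))
      cb <- as.integer(rmultinom(1, sample(2:10, 1), runif(3, 0.05, 1)))
      poly <- (ca[2] + cb[2] + ca[3] + cb[3] > 0) &&
        (ca[2] + cb[2] + ca[1] + cb[1] > 0)
      if (poly) break
    }
    fx <- make_pair_matrix(ca, cb)
    got <- weir_cockerham_fst(fx$x, fx$pm, "A", "B")$theta
    if (!is.na(got)) {
      expect_equal(got, wc_theta_oracle(ca, cb), tolerance = 1e-10)
    }
  }
})

test_that("Reynolds-style A/B components match the published-formula oracle", {
  p1 <- c(1, 0.5, 0.2, 0, 0.9)
  p2 <- c(0, 0.5, 0.8, 0, 0.1)
  res <- reynolds_fst(p1, p2, n1 = 8, n2 = 6)
  for (j in seq_along(p1)) {
    ab <- hudson_ab_oracle(p1[j], p2[j], 8, 6)
    expect_equal(res$A[j], unname(ab["A"]), tolerance = 1e-12)
    expect_equal(res$B[j], unname(ab["B"]), tolerance = 1e-12)
  }
  expect_equal(res$weighted_fst, sum(res$A) / sum(res$B))

  fixed <- reynolds_fst(rep(1, 5), rep(0, 5), 8, 6)
  expect_equal(fixed$weighted_fst, 1)
  expect_equal(fixed$unweighted_fst, 1)

  same <- reynolds_fst(rep(0.4, 50), rep(0.4, 50), 10, 10)
  expect_lte(same$unweighted_fst, 0)
  expect_lt(abs(same$weighted_fst), 0.1)
})

test_that("monomorphic sites drop out of the weighted sum and the ratio mean", {
  set.seed(41)
  p1 <- c(runif(10, 0.6, 1), rep(0, 990))
  p2 <- c(runif(10, 0, 0.4), rep(0, 990))
  res <- reynolds_fst(p1, p2, 10, 10)
  only_var <- reynolds_fst(p1[1:10], p2[1:10], 10, 10)
  expect_equal(res$weighted_fst, only_var$weighted_fst, tolerance = 1e-12)
  expect_equal(res$unweighted_fst, only_var$unweighted_fst, tolerance = 1e-12)
  expect_equal(res$n_sites, 10L)
  # both summaries equal direct evaluation of the component sums/ratios
  AB <- vapply(1:10, function(j) hudson_ab_oracle(p1[j], p2[j], 10, 10), c(A = 0, B = 0))
  expect_equal(res$weighted_fst, sum(AB["A", ]) / sum(AB["B", ]), tolerance = 1e-12)
  expect_equal(res$unweighted_fst, mean(AB["A", ] / AB["B", ]), tolerance = 1e-12)
})

test_that("ratio-of-sums W&C and Reynolds F_ST agree on balanced simulated pairs", {
  ds <- simulate_island_model(island_model_config(
    n_demes = 2, deme_size = 300, migration_rate = 1 / 1200, n_sites = 3000,
    n_generations = 1500, sample_sizes = 25, seed = 55))
  tab <- pairwise_stats(ds$genotypes, ds$population_map)
  wc <- weir_cockerham_fst(ds$genotypes, ds$population_map, "deme1", "deme2")
  expect_lt(abs(wc$weighted_fst - tab$weighted_fst), 0.02)
})

test_that("d_XY follows its algebraic identities", {
  expect_equal(dxy(1, 0)$dxy, 1)
  expect_equal(dxy(0.5, 0.5)$dxy, 0.5)
  p <- seq(0, 1, by = 0.1)
  expect_equal(dxy(p, p)$dxy, 2 * p * (1 - p))
  # joint REF/ALT relabeling leaves d_XY unchanged
  x <- runif(20); y <- runif(20)
  expect_equal(dxy(1 - x, 1 - y)$dxy, dxy(x, y)$dxy)
  expect_error(dxy(1.2, 0.5), "0, 1")
})

test_that("island-model migration inversion is exact and monotone", {
  expect_equal(migration_from_fst(0.5)$M, 1)
  expect_equal(migration_from_fst(0.2)$M, 4)
  est <- migration_from_fst(0.5, ne = 1e5)
  expect_equal(est$m, 2.5e-6)
  Ms <- vapply(seq(0.05, 0.95, by = 0.05),
               function(f) migration_from_fst(f)$M, 0)
  expect_true(all(diff(Ms) < 0))
  expect_warning(res <- migration_from_fst(-0.01), "undefined")
  expect_false(res$defined)
  expect_equal(migration_from_fst(1)$M, 0)
})

test_that("global F_ST is defined and exceeds zero under structure", {
  ds <- simulate_island_model(island_model_config(
    n_demes = 4, deme_size = 100, migration_rate = 1 / 400, n_sites = 500,
    n_generations = 600, sample_sizes = 8, seed = 77))
  g <- global_fst(ds$genotypes, ds$population_map)
  expect_gt(g$fst, 0.1)
  expect_lt(g$fst, 1)
  expect_equal(length(g$hs), n_sites(ds$genotypes))
})
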