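# Genotype-likelihood diversity chain: frequency EM, count-likelihood DP,
# folded-SFS EM, and pi from count posteriors.

test_that("allele-frequency EM finds the obvious optima", {
  hom <- toy_gl(matrix(0L, 8, 1), conf = 0.9999)
  expect_lt(gl_allele_frequency(site_linear_gl(hom, 1))$p_hat, 1e-3)

  half <- toy_gl(matrix(c(rep(0L, 5), rep(2L, 5)), 10, 1), conf = 0.9999)
  expect_equal(gl_allele_frequency(site_linear_gl(half, 1))$p_hat, 0.5,
               tolerance = 1e-3)

  flat <- matrix(1, 10, 3)
  fit <- gl_allele_frequency(flat)
  expect_true(fit$flat)
  grid <- vapply(seq(0, 1, 0.1), fit$loglik, 0)
  expect_lt(diff(range(grid)), 1e-12)
})

test_that("count-likelihood DP equals exhaustive enumeration", {
  set.seed(19)
  for (rep in 1:10) {
    lik <- random_gl_matrix(3)
    expect_equal(allele_count_likelihoods(lik), acl_oracle(lik),
                 tolerance = 1e-10)
  }
  # concentrated cases
  hom <- matrix(rep(c(1, 1e-8, 1e-8), each = 3), 3, 3)
  v <- allele_count_likelihoods(hom)
  expect_equal(which.max(v), 1L)
  one_het <- rbind(c(1e-8, 1, 1e-8), c(1, 1e-8, 1e-8), c(1, 1e-8, 1e-8))
  expect_equal(which.max(allele_count_likelihoods(one_het)), 2L)
})

test_that("folded-SFS EM concentrates on class 0 for monomorphic data and is monotone", {
  geno <- matrix(0L, 6, 50)
  gl <- toy_gl(geno, conf = 0.9999)
  acl <- cavepop:::population_count_likelihoods(gl)
  sfs <- folded_sfs_em(acl)
  expect_gt(sfs$proportions[1], 0.99)
  expect_true(all(diff(sfs$loglik) > -1e-9))
  expect_equal(sum(sfs$proportions), 1, tolerance = 1e-8)
})

test_that("high-depth folded SFS matches the hard-call folded histogram", {
  ds <- simulate_island_model(island_model_config(
    n_demes = 2, deme_size = 80, migration_rate = 0.1, n_sites = 300,
    n_generations = 200, sample_sizes = 5, seed = 33))
  rows <- 1:5
  g <- ds$genotypes$dosage[rows, ]
  gl <- toy_gl(g, conf = 0.999999)
  acl <- cavepop:::population_count_likelihoods(gl)[, , drop = FALSE]
  sfs <- folded_sfs_em(acl, max_iter = 3000)
  mac <- pmin(colSums(g), 10L - colSums(g))
  hard_hist <- tabulate(mac + 1L, nbins = 6L)
  expect_true(all(abs(sfs$counts - hard_hist) < 1))
})

test_that("pi from count posteriors matches the documented arithmetic", {
  # a single site whose likelihood is concentrated at count N of 2N
  acl <- matrix(1e-12, 1, 11)
  acl[1, 6] <- 1
  sfs <- folded_sfs_em(acl)
  est <- pi_from_sfs(acl, sfs, total_positions = 1)
  expect_equal(est$pi_per_site, 5 * 5 / 45, tolerance = 1e-6)

  mono <- matrix(c(1, rep(1e-14, 10)), 3, 11, byrow = TRUE)
  sfs0 <- folded_sfs_em(mono)
  expect_lt(pi_from_sfs(mono, sfs0, 3)$pi_per_site, 1e-6)
})

test_that("GL pi converges to hard-call pi at high depth", {
  ds <- simulate_island_model(island_model_config(
    n_demes = 2, deme_size = 100, migration_rate = 0.05, n_sites = 800,
    n_generations = 300, sample_sizes = 8, seed = 61))
  rd <- simulate_reads(ds, read_observation_config(mean_depth = 100,
                                                   error_rate = 0.001, seed = 8))
  pm <- ds$population_map
  hard <- pi_hard(ds$genotypes, pm, "deme1", total_positions = 800)
  soft <- pi_gl(rd$gl, pm, "deme1", total_positions = 800)
  expect_lt(abs(soft$pi_per_site - hard$pi_per_site) / hard$pi_per_site, 0.02)
})

test_that("pi is invariant to REF/ALT relabeling", {
  set.seed(3)
  d <- matrix(sample(0:2, 80, replace = TRUE), 8, 10)
  pm <- popmap(paste0("S", 1:8), rep("c", 8))
  a <- pi_hard(toy_geno(d), pm, "c", total_positions = 10)$pi_per_site
  b <- pi_hard(toy_geno(2L - d), pm, "c", total_positions = 10)$pi_per_site
  expect_equal(a, b)
  gl <- toy_gl(d, conf = 0.999)
  gl_swap <- toy_gl(2L - d, conf = 0.999)
  pa <- pi_gl(gl, pm, "c", total_positions = 10)$pi_per_site
  pb <- pi_gl(gl_swap, pm, "c", total_positions = 10)$pi_per_site
  expect_equal(pa, pb, tolerance = 1e-6)
})
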