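# Hard-call and genotype-likelihood site filters.

test_that("singleton and call-rate rules remove the documented example sites", {
  # 10 samples x 3 sites: site 1 fine, site 2 singleton, site 3 low call rate
  d <- cbind(c(rep(0L, 5), rep(1L, 5)),
             c(1L, rep(0L, 9)),
             c(rep(0L, 7), NA, NA, NA))
  x <- toy_geno(d)
  res <- filter_hard_calls(x, hard_filter_params(min_genotype_depth = 0,
                                                 excess_het_p_threshold = 0))
  expect_equal(res$report$rules$removed,
               c(0L, 1L, 1L, 0L))            # biallelic, call-rate, singleton, het
  expect_equal(n_sites(res$matrix), 1L)
  expect_equal(res$matrix$sites$pos, 1L)
})

test_that("low-depth genotypes are masked before site rules", {
  d <- matrix(c(0L, 1L, 0L, 1L), 4, 1)
  dp <- matrix(c(1L, 1L, 5L, 5L), 4, 1)
  x <- toy_geno(d, depth = dp)
  res <- filter_hard_calls(x, hard_filter_params(min_genotype_depth = 2,
                                                 min_call_rate = 0,
                                                 drop_singletons = FALSE,
                                                 excess_het_p_threshold = 0))
  expect_identical(unname(res$matrix$dosage[, 1]), c(NA, NA, 0L, 1L))
  expect_error(filter_hard_calls(toy_geno(d), hard_filter_params()), "depth")
})

test_that("an all-heterozygote site is removed by the excess-het rule", {
  d <- cbind(rep(1L, 10), c(rep(0L, 5), rep(2L, 5)))
  x <- toy_geno(d)
  expect_lt(hwe_excess_het_p(0, 10, 0), 0.1)
  res <- filter_hard_calls(x, hard_filter_params(min_genotype_depth = 0,
                                                 min_call_rate = 0,
                                                 drop_singletons = FALSE))
  expect_equal(res$report$rules$removed[4], 1L)
  expect_equal(res$matrix$sites$pos, 2L)
})

test_that("exact heterozygote-excess p-values match enumeration", {
  expect_equal(hwe_excess_het_p(5, 0, 0), 1)
  expect_equal(hwe_excess_het_p(0, 2, 0), 2 / 3)  # frozen: enumeration over 2 diploids
  expect_equal(hwe_excess_het_p(0, 2, 0), hwe_excess_oracle(0, 2, 0))
  # more heterozygotes at fixed allele counts means smaller excess-het p
  expect_lt(hwe_excess_het_p(2, 6, 2), hwe_excess_het_p(4, 2, 4))
  for (n in 1:6) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      p <- hwe_excess_het_p(n0, n1, n2)
      expect_gte(p, 0)
      expect_lte(p, 1)
      expect_equal(p, hwe_excess_oracle(n0, n1, n2), tolerance = 1e-12)
    }
  }
})

test_that("filter reports conserve site counts and filtering is idempotent", {
  set.seed(31)
  for (rep in 1:5) {
    d <- matrix(sample(c(0:2, NA), 200, replace = TRUE, prob = c(.4, .2, .3, .1)),
                10, 20)
    x <- toy_geno(d)
    res <- suppressWarnings(
      filter_hard_calls(x, hard_filter_params(min_genotype_depth = 0,
                                              min_call_rate = 0.8)))
    expect_equal(res$report$n_input,
                 res$report$n_retained + sum(res$report$rules$removed))
    twice <- suppressWarnings(
      filter_hard_calls(res$matrix, hard_filter_params(min_genotype_depth = 0,
                                                       min_call_rate = 0.8)))
    expect_identical(twice$matrix$dosage, res$matrix$dosage)
    expect_equal(sum(twice$report$rules$removed), 0L)
  }
})

test_that("GL filters drop under-represented, non-SNP and het-majority sites", {
  # 10 samples x 4 sites: 1 = real SNP, 2 = 30% missing, 3 = monomorphic,
  # 4 = all confidently heterozygous (paralog signature)
  geno <- cbind(c(rep(0L, 5), rep(2L, 5)),
                c(rep(0L, 4), rep(2L, 3), NA, NA, NA),
                rep(0L, 10),
                rep(1L, 10))
  gl <- toy_gl(geno, conf = 0.9999)
  res <- filter_gl_sites(gl, gl_filter_params())
  expect_equal(res$report$rules$rule, c("representation", "snp_lrt", "het_majority"))
  expect_equal(res$report$rules$removed, c(1L, 1L, 1L))
  expect_equal(res$tensor$sites$pos, 1L)
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(res$report$rules$removed))
})

test_that("the SNP likelihood-ratio statistic matches direct likelihood evaluation", {
  geno <- matrix(c(rep(0L, 6), rep(1L, 3), 2L), 10, 1)
  gl <- toy_gl(geno, conf = 0.99)
  lin <- site_linear_gl(gl, 1)
  fit <- gl_allele_frequency(lin)
  direct <- function(p) {
    w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum(log(lin %*% w))
  }
  expect_equal(fit$ll_max, direct(fit$p_hat), tolerance = 1e-9)
  # EM optimum beats a fine grid
  grid <- seq(0.001, 0.999, by = 0.001)
  expect_gte(fit$ll_max + 1e-8, max(vapply(grid, direct, 0)))
  ts <- gl_snp_test(lin)
  expect_equal(ts$statistic, 2 * (fit$ll_max - max(direct(0), direct(1))),
               tolerance = 1e-9)
})
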