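# Island-model simulator: determinism, migration/drift behavior, and the
# read-observation layer.

test_that("invalid configurations are rejected with the parameter named", {
  expect_error(island_model_config(n_demes = 1, migration_rate = 0.1), "n_demes")
  expect_error(island_model_config(migration_rate = 1.5), "migration_rate")
  expect_error(island_model_config(migration_rate = 0.1, deme_size = 0), "deme_size")
  expect_error(island_model_config(migration_rate = 0.1, sample_sizes = 600,
                                   deme_size = 500), "sample_sizes")
  expect_error(read_observation_config(mean_depth = -1), "mean_depth")
  expect_error(read_observation_config(error_rate = 0.7), "error_rate")
})

test_that("simulation is bit-identical given the same seed and leaves the RNG alone", {
  cfg <- island_model_config(migration_rate = 0.01, n_sites = 100,
                             n_generations = 50, deme_size = 50,
                             sample_sizes = 4, seed = 11)
  set.seed(99)
  before <- .Random.seed
  a <- simulate_island_model(cfg)
  expect_identical(before, .Random.seed)
  b <- simulate_island_model(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$true_freqs, b$true_freqs)
  c_ <- simulate_island_model(island_model_config(migration_rate = 0.01,
                                                  n_sites = 100,
                                                  n_generations = 50,
                                                  deme_size = 50,
                                                  sample_sizes = 4, seed = 12))
  expect_false(identical(a$genotypes$dosage, c_$genotypes$dosage))
})

test_that("free migration homogenizes demes and isolation drives fixation", {
  free <- simulate_island_model(island_model_config(
    n_demes = 4, deme_size = 100, migration_rate = 0.5, n_sites = 500,
    n_generations = 2000, sample_sizes = 8, seed = 21))
  tab <- pairwise_stats(free$genotypes, free$population_map)
  expect_lt(mean(tab$weighted_fst), 0.02)

  iso <- simulate_island_model(island_model_config(
    n_demes = 4, deme_size = 100, migration_rate = 0, n_sites = 500,
    n_generations = 2000, sample_sizes = 8, seed = 22))
  # most sites fixed within demes after 20 Ne generations of pure drift
  fixed <- mean(iso$true_freqs == 0 | iso$true_freqs == 1)
  expect_gt(fixed, 0.9)
  tab <- pairwise_stats(iso$genotypes, iso$population_map)
  expect_gt(mean(tab$weighted_fst), 0.8)
})

test_that("within-deme heterozygosity declines under pure drift", {
  het_at <- function(gens, seed) {
    ds <- simulate_island_model(island_model_config(
      n_demes = 2, deme_size = 50, migration_rate = 0, n_sites = 400,
      n_generations = gens, sample_sizes = 5, seed = seed))
    mean(2 * ds$true_freqs * (1 - ds$true_freqs))
  }
  early <- mean(vapply(1:5, function(s) het_at(20, s), 0))
  late <- mean(vapply(1:5, function(s) het_at(200, s), 0))
  expect_lt(late, early)
})

test_that("weighted F_ST decreases as migration increases", {
  fst_at <- function(fourNm, seed) {
    ds <- simulate_island_model(island_model_config(
      n_demes = 4, deme_size = 100, migration_rate = fourNm / 400,
      n_sites = 600, n_generations = 800, sample_sizes = 8, seed = seed))
    mean(pairwise_stats(ds$genotypes, ds$population_map)$weighted_fst)
  }
  means <- vapply(c(0.25, 1, 4), function(fourNm) {
    mean(vapply(1:4, function(s) fst_at(fourNm, 30 + s), 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("read simulation recovers genotypes at high depth and respects depth 0", {
  ds <- simulate_island_model(island_model_config(
    migration_rate = 0.01, n_sites = 300, n_generations = 100,
    deme_size = 50, sample_sizes = 5, seed = 41))
  rd <- simulate_reads(ds, read_observation_config(mean_depth = 100,
                                                   error_rate = 0.001, seed = 2))
  called <- call_genotypes(rd$gl, rd$depth)
  ok <- !is.na(called$dosage)
  expect_gt(mean(called$dosage[ok] == ds$genotypes$dosage[ok]), 0.999)
  expect_identical(which(rd$depth == 0L), which(rd$gl$missing))

  empty <- simulate_reads(ds, read_observation_config(mean_depth = 0, seed = 2))
  expect_true(all(empty$gl$missing))
})

test_that("likelihood triples match the binomial read model", {
  ds <- simulate_island_model(island_model_config(
    migration_rate = 0.01, n_sites = 200, n_generations = 50,
    deme_size = 50, sample_sizes = 5, seed = 43))
  e <- 0.01
  rd <- simulate_reads(ds, read_observation_config(mean_depth = 4,
                                                   error_rate = e, seed = 5))
  hit <- which(rd$depth == 4L & rd$alt_reads == 2L)[1]
  expect_false(is.na(hit))
  ij <- arrayInd(hit, dim(rd$depth))
  triple <- exp(rd$gl$loglik[ij[1], ij[2], ])
  hand <- vapply(c(e, 0.5, 1 - e), function(p) 6 * p^2 * (1 - p)^2, 0)
  expect_equal(unname(triple), hand, tolerance = 1e-12)
})
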