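#' Island-model simulation configuration
#'
#' Describes a finite island model: `n_demes` demes of constant diploid
#' size `deme_size` exchange migrants symmetrically at rate
#' `migration_rate` per allele copy per generation, and each of `n_sites`
#' unlinked biallelic loci drifts by binomial Wright-Fisher resampling for
#' `n_generations` generations from a shared ancestral frequency drawn
#' uniformly from `ancestral_freq_range`. Migration acts as deterministic
#' frequency mixing toward the mean of the other demes before resampling,
#' which gives the classical finite-island equilibrium
#' `E(FST) = 1 / (1 + 4*N*m*(d/(d-1))^2)`. Optionally, symmetric recurrent
#' mutation at `mutation_rate` per allele copy per generation can be
#' enabled (off by default: variation enters through ancestral
#' frequencies).
#'
#' @param n_demes Number of demes (>= 2).
#' @param deme_size Diploid effective size per deme.
#' @param migration_rate Per-generation migrant fraction m in \[0, 1\].
#' @param n_sites Number of independent loci.
#' @param n_generations Generations of drift.
#' @param ancestral_freq_range Length-2 range for the uniform ancestral
#'   allele-frequency draw.
#' @param sample_sizes Individuals sampled per deme; a single value is
#'   recycled. Each must be between 1 and `deme_size`.
#' @param mutation_rate Symmetric per-copy mutation probability per
#'   generation (default 0).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   configuration.
#' @return An object of class `island_model_config`.
#' @export
island_model_config <- function(n_demes = 4, deme_size = 500, migration_rate,
                                n_sites = 5000, n_generations = 2000,
                                ancestral_freq_range = c(0.05, 0.95),
                                sample_sizes = 10, mutation_rate = 0,
                                seed = 1) {
  check_scalar(n_demes, "n_demes", lower = 2, integer = TRUE)
  check_scalar(deme_size, "deme_size", lower = 1, integer = TRUE)
  check_scalar(migration_rate, "migration_rate", lower = 0, upper = 1)
  check_scalar(n_sites, "n_sites", lower = 1, integer = TRUE)
  check_scalar(n_generations, "n_generations", lower = 0, integer = TRUE)
  check_scalar(mutation_rate, "mutation_rate", lower = 0, upper = 0.5)
  check_scalar(seed, "seed", integer = TRUE)
  if (length(ancestral_freq_range) != 2L || any(ancestral_freq_range < 0) ||
      any(ancestral_freq_range > 1) || diff(ancestral_freq_range) < 0) {
    stop("`ancestral_freq_range` must be an increasing pair in [0, 1]",
         call. = FALSE)
  }
  sample_sizes <- as.integer(rep_len(sample_sizes, n_demes))
  if (any(sample_sizes < 1L) || any(sample_sizes > deme_size)) {
    stop("`sample_sizes` must each be in [1, deme_size]", call. = FALSE)
  }
  structure(list(n_demes = as.integer(n_demes), deme_size = as.integer(deme_size),
                 migration_rate = migration_rate, n_sites = as.integer(n_sites),
                 n_generations = as.integer(n_generations),
                 ancestral_freq_range = ancestral_freq_range,
                 sample_sizes = sample_sizes, mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "island_model_config")
}

#' Simulate an island-model RAD-seq genotype dataset
#'
#' Runs the Wright-Fisher island model described by
#' [island_model_config()], then draws `sample_sizes` diploid individuals
#' per deme under Hardy-Weinberg proportions at the final deme allele
#' frequencies. Loci are unlinked; sites fixed during the simulation are
#' retained (downstream filters deal with them).
#'
#' @param config An [island_model_config()].
#' @return An object of class `simulated_dataset`: a list with
#'   `true_freqs` (demes x sites final allele frequencies), `genotypes`
#'   (a [genotype_matrix()] without depth), `population_map` (a
#'   [popmap()] with labels `deme1..demeD`), and `provenance` (the
#'   configuration).
#' @export
simulate_island_model <- function(config) {
  if (!inherits(config, "island_model_config")) {
    stop("`config` must be an island_model_config", call. = FALSE)
  }
  d <- config$n_demes
  L <- config$n_sites
  N2 <- 2L * config$deme_size
  m <- config$migration_rate
  mu <- config$mutation_rate
  with_seed(config$seed, {
    p0 <- runif(L, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
    freqs <- matrix(rep(p0, each = d), nrow = d)   # demes x sites
    for (g in seq_len(config$n_generations)) {
      if (m > 0 && d > 1) {
        others <- (rep(colSums(freqs), each = d) - freqs) / (d - 1)
        freqs <- (1 - m) * freqs + m * others
      }
      if (mu > 0) freqs <- freqs * (1 - mu) + (1 - freqs) * mu
      freqs <- matrix(rbinom(d * L, N2, freqs), nrow = d) / N2
    }
    n_ind <- sum(config$sample_sizes)
    deme_of <- rep(seq_len(d), config$sample_sizes)
    dosage <- matrix(rbinom(n_ind * L, 2L, freqs[deme_of, ]), nrow = n_ind)
    samples <- paste0("deme", deme_of, "_ind",
                      sprintf("%02d", sequence(config$sample_sizes)))
    sites <- data.frame(chrom = "chr1", pos = seq_len(L),
                        ref = "A", alt = "C", stringsAsFactors = FALSE)
    structure(list(
      true_freqs = freqs,
      genotypes = genotype_matrix(dosage, sites = sites, samples = samples),
      population_map = popmap(samples, paste0("deme", deme_of)),
      provenance = config
    ), class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cfg <- x$provenance
  cat(sprintf("<simulated_dataset> %d demes (N=%d, m=%g), %d sites, %d samples\n",
              cfg$n_demes, cfg$deme_size, cfg$migration_rate, cfg$n_sites,
              n_samples(x$genotypes)))
  invisible(x)
}

#' Read-observation configuration
#'
#' Sequencing-emulation settings used by [simulate_reads()]: per-genotype
#' read depth is Poisson with mean `mean_depth`, and each read reports the
#' alternate base with probability `error_rate`, `0.5`, or
#' `1 - error_rate` for genotypes 0, 1 and 2.
#'
#' @param mean_depth Expected reads per genotype (>= 0).
#' @param error_rate Per-base error probability in \[0, 0.5).
#' @param missing_if_zero_depth Flag genotypes with zero reads as missing
#'   (default `TRUE`; the likelihood triple is uninformative either way).
#' @param seed Integer seed.
#' @return An object of class `read_observation_config`.
#' @export
read_observation_config <- function(mean_depth = 5, error_rate = 0.01,
                                    missing_if_zero_depth = TRUE, seed = 1) {
  check_scalar(mean_depth, "mean_depth", lower = 0)
  check_scalar(error_rate, "error_rate", lower = 0, upper = 0.5 - 1e-12)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 missing_if_zero_depth = isTRUE(missing_if_zero_depth),
                 seed = as.integer(seed)),
            class = "read_observation_config")
}

#' Emulate read observation and genotype likelihoods
#'
#' Draws a read depth and alternate-read count for every genotype in a
#' [genotype_matrix()] (or the genotypes of a `simulated_dataset`) and
#' evaluates the likelihood of each candidate genotype under the same
#' binomial read model: with depth `D`, alternate count `a` and error rate
#' `e`, `L(g) = C(D, a) * p_g^a * (1 - p_g)^(D - a)` for
#' `p_g in {e, 1/2, 1 - e}`. Zero-depth entries are missing.
#'
#' @param dataset A `simulated_dataset` or [genotype_matrix()].
#' @param config A [read_observation_config()].
#' @return A list with `gl` (a [gl_tensor()]), `depth` and `alt_reads`
#'   (samples x sites integer matrices).
#' @export
simulate_reads <- function(dataset, config) {
  if (inherits(dataset, "simulated_dataset")) dataset <- dataset$genotypes
  if (!inherits(dataset, "genotype_matrix")) {
    stop("`dataset` must be a simulated_dataset or genotype_matrix", call. = FALSE)
  }
  if (!inherits(config, "read_observation_config")) {
    stop("`config` must be a read_observation_config", call. = FALSE)
  }
  g <- dataset$dosage
  n <- nrow(g); m <- ncol(g)
  e <- config$error_rate
  p_alt <- c(e, 0.5, 1 - e)
  with_seed(config$seed, {
    depth <- matrix(rpois(n * m, config$mean_depth), n, m)
    depth[is.na(g)] <- 0L
    gi <- g
    gi[is.na(gi)] <- 0L                      # depth already forced to 0 there
    alt <- matrix(rbinom(n * m, depth, p_alt[gi + 1L]), n, m)
    ll <- array(NA_real_, dim = c(n, m, 3))
    for (k in 1:3) {
      ll[, , k] <- dbinom(alt, depth, p_alt[k], log = TRUE)
    }
    miss <- depth == 0L
    if (config$missing_if_zero_depth) {
      ll[rep(miss, 3)] <- -Inf
    }
    gl <- gl_tensor(ll, sites = dataset$sites, samples = dataset$samples,
                    missing = miss)
    list(gl = gl, depth = depth, alt_reads = alt)
  })
}

#' Hard-call genotypes from likelihoods
#'
#' Maximum-likelihood genotype per entry (ties broken toward the smaller
#' dosage), missing where the likelihood triple is missing. This emulates
#' a hard-calling track run on the same reads as the likelihood track.
#'
#' @param gl A [gl_tensor()].
#' @param depth Optional depth matrix to attach to the result.
#' @return A [genotype_matrix()].
#' @export
call_genotypes <- function(gl, depth = NULL) {
  n <- n_samples(gl); m <- n_sites(gl)
  flat <- matrix(gl$loglik, nrow = n * m, ncol = 3)
  call <- max.col(flat, ties.method = "first") - 1L
  call[as.vector(gl$missing)] <- NA_integer_
  genotype_matrix(matrix(call, n, m), sites = gl$sites, depth = depth,
                  samples = gl$samples)
}
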