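#' Expected heterozygosity at a site
#'
#' Unbiased (small-sample corrected) expected heterozygosity
#' `h = n/(n-1) * (1 - sum(p_i^2))`, where `n` is the number of sequences
#' (allele copies) observed at the site and `p_i` the sample frequency of
#' allele `i`.
#'
#' @param n_ref,n_alt Counts of reference and alternate allele copies
#'   among non-missing genotypes (vectors allowed, recycled together).
#' @return `h` per site; `NA` where fewer than 2 sequences were observed.
#' @export
expected_het <- function(n_ref, n_alt) {
  if (any(n_ref < 0) || any(n_alt < 0)) {
    stop("allele counts must be non-negative", call. = FALSE)
  }
  n <- n_ref + n_alt
  p <- ifelse(n > 0, n_alt / n, NA_real_)
  h <- n / (n - 1) * (1 - p^2 - (1 - p)^2)
  h[n < 2] <- NA_real_
  h
}

#' Nucleotide diversity from hard genotype calls
#'
#' Sums per-site expected heterozygosities over segregating sites and
#' divides by the total number of interrogated positions:
#' `pi = sum_j h_j / total_positions`. The per-site `n` is twice the
#' number of non-missing genotypes at that site in the focal population.
#'
#' @param x A [genotype_matrix()].
#' @param pm A [popmap()] covering the samples of `x`.
#' @param population Population label to summarize.
#' @param total_positions Denominator: the number of positions
#'   interrogated for variants (not just the segregating ones). Defaults
#'   to the number of sites in `x`, which is only appropriate when `x`
#'   spans all interrogated positions.
#' @param mu Per-site per-generation mutation rate used for the
#'   `Ne = pi / (4 mu)` conversion.
#' @param n_blocks If > 1, sites are split into this many contiguous
#'   equal-count blocks and a per-block pi is also returned, for variance
#'   assessment.
#' @return A `diversity_estimate`: list with `population`, `pi_per_site`,
#'   `S` (segregating sites), `total_positions`, `method`, `mu`, `ne`,
#'   and optionally `block_pi`.
#' @export
pi_hard <- function(x, pm, population, total_positions = n_sites(x),
                    mu = 2.8e-9, n_blocks = 1) {
  rows <- pop_rows(x, pm, population)
  counts <- site_geno_counts(x, rows)
  n_alt <- 2L * counts[, "n2"] + counts[, "n1"]
  n_ref <- 2L * counts[, "n0"] + counts[, "n1"]
  h <- expected_het(n_ref, n_alt)
  seg <- !is.na(h) & n_alt > 0L & n_ref > 0L
  S <- sum(seg)
  if (total_positions < S) {
    stop("`total_positions` must be at least the number of segregating sites",
         call. = FALSE)
  }
  pi <- sum(h[seg]) / total_positions
  out <- diversity_estimate(population, pi, S, total_positions, "hard-call", mu)
  if (n_blocks > 1) {
    block <- cut(seq_len(n_sites(x)), n_blocks, labels = FALSE)
    hh <- ifelse(seg, h, 0)
    out$block_pi <- as.numeric(tapply(hh, block, sum)) /
      (total_positions / n_blocks)
  }
  out
}

diversity_estimate <- function(population, pi, S, total_positions, method, mu) {
  structure(list(population = population, pi_per_site = pi, S = S,
                 total_positions = total_positions, method = method,
                 mu = mu, ne = ne_from_pi(pi, mu)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> %s [%s]: pi/site = %.3g (S = %d / %d positions), Ne = %.3g\n",
              x$population, x$method, x$pi_per_site, x$S, x$total_positions, x$ne),
      sprintf("  (Ne assumes mu = %.3g per site per generation; treat as order-of-magnitude)\n",
              x$mu), sep = "")
  invisible(x)
}

#' Effective population size from nucleotide diversity
#'
#' Neutral-equilibrium conversion `Ne = pi / (4 mu)`.
#'
#' @param pi_per_site Per-site nucleotide diversity.
#' @param mu Per-site per-generation mutation rate; the default 2.8e-9 is
#'   a Drosophila estimate commonly borrowed for arthropods without their
#'   own rate — resulting Ne values are order-of-magnitude only.
#' @return Effective population size estimate.
#' @export
ne_from_pi <- function(pi_per_site, mu = 2.8e-9) {
  check_scalar(mu, "mu", lower = 1e-300)
  if (any(pi_per_site < 0)) stop("`pi_per_site` must be non-negative", call. = FALSE)
  pi_per_site / (4 * mu)
}
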