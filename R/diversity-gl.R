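# Genotype-likelihood track of the diversity module: per-site allele
# frequency by EM, the dynamic-programming likelihood of each total
# minor-allele count, the folded site-frequency-spectrum EM across sites,
# and nucleotide diversity from the SFS-prior count posteriors.

#' Maximum-likelihood allele frequency from genotype likelihoods
#'
#' Maximizes `sum_i log sum_g L_i(g) P(g | p)` over the alternate-allele
#' frequency `p`, with Hardy-Weinberg genotype priors
#' `P(g | p) = C(2, g) p^g (1-p)^(2-g)`, by EM.
#'
#' @param lik Numeric matrix `samples x 3` of linear-scale genotype
#'   likelihoods for one site (any per-row scaling); rows that are all
#'   `NA` are treated as missing.
#' @param tol EM convergence tolerance on `p` (default 1e-10).
#' @param max_iter Maximum EM iterations.
#' @return List with `p_hat`, `loglik` (a function of `p`), `ll_max`,
#'   `n_used`, and `flat` (`TRUE` when the likelihood surface is constant,
#'   e.g. all triples uninformative, in which case `p_hat` is arbitrary).
#' @export
gl_allele_frequency <- function(lik, tol = 1e-10, max_iter = 200) {
  lik <- as.matrix(lik)
  if (ncol(lik) != 3L) stop("`lik` must have 3 columns", call. = FALSE)
  keep <- rowSums(is.na(lik)) == 0L & rowSums(lik) > 0
  lik <- lik[keep, , drop = FALSE]
  n <- nrow(lik)
  if (n == 0L) stop("no non-missing genotype likelihoods at site", call. = FALSE)
  loglik <- function(p) {
    w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum(log(lik %*% w))
  }
  p <- 0.25
  for (it in seq_len(max_iter)) {
    w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    post <- lik * rep(w, each = n)
    post <- post / rowSums(post)
    p_new <- sum(post %*% c(0, 1, 2)) / (2 * n)
    if (abs(p_new - p) < tol) { p <- p_new; break }
    p <- p_new
  }
  grid <- vapply(c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1), loglik, 0)
  flat <- diff(range(grid)) < 1e-12
  list(p_hat = p, loglik = loglik, ll_max = loglik(p), n_used = n, flat = flat)
}

#' SNP likelihood-ratio test from genotype likelihoods
#'
#' Tests polymorphism at a site: the alternative is the ML allele
#' frequency, the null is monomorphism at whichever allele is more likely
#' (`max` of the log-likelihoods at `p = 0` and `p = 1`). The statistic
#' `2 (l(p_hat) - l_0)` is referred to a chi-square with 1 df.
#'
#' @inheritParams gl_allele_frequency
#' @return List with `p_value`, `statistic`, `p_hat`.
#' @export
gl_snp_test <- function(lik) {
  fit <- gl_allele_frequency(lik)
  ll0 <- max(fit$loglik(0), fit$loglik(1))
  stat <- max(0, 2 * (fit$ll_max - ll0))
  list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat, p_hat = fit$p_hat)
}

#' Likelihood of each total alternate-allele count at a site
#'
#' Dynamic programming over individuals: the probability of the observed
#' read data given that the `N` diploids jointly carry `c` alternate
#' alleles, marginalizing over genotype configurations with the
#' hypergeometric composition weight `prod C(2, g_i) / C(2N, c)`.
#' Missing individuals contribute a flat likelihood triple, so every site
#' yields the same `2N + 1` count classes.
#'
#' @param lik Numeric matrix `N x 3` of linear genotype likelihoods
#'   (all-`NA` rows = missing).
#' @return Numeric vector of length `2N + 1` (counts `0..2N`), rescaled
#'   to maximum 1.
#' @export
allele_count_likelihoods <- function(lik) {
  lik <- as.matrix(lik)
  if (ncol(lik) != 3L) stop("`lik` must have 3 columns", call. = FALSE)
  N <- nrow(lik)
  if (N < 1L) stop("need at least one individual", call. = FALSE)
  miss <- rowSums(is.na(lik)) > 0L | rowSums(lik, na.rm = TRUE) <= 0
  lik[miss, ] <- 1
  h <- 1
  for (i in seq_len(N)) {
    v <- lik[i, ] * c(1, 2, 1)              # C(2, g) composition factors
    h <- c(h, 0, 0) * v[1] +
         c(0, h, 0) * v[2] +
         c(0, 0, h) * v[3]
    mx <- max(h)
    if (mx > 0) h <- h / mx
  }
  h <- h / choose(2 * N, 0:(2 * N))
  h / max(h)
}

# Site x (2N+1) matrix of count likelihoods for one population.
population_count_likelihoods <- function(gl, pm = NULL, population = NULL) {
  rows <- if (is.null(pm)) seq_len(n_samples(gl)) else pop_rows(gl, pm, population)
  m <- n_sites(gl)
  N <- length(rows)
  out <- matrix(NA_real_, m, 2 * N + 1)
  for (j in seq_len(m)) {
    lin <- site_linear_gl(gl, j)[rows, , drop = FALSE]
    out[j, ] <- allele_count_likelihoods(lin)
  }
  out
}

# Fold site count likelihoods: class j in 0..N collects counts j and 2N-j
# (the j = N self-conjugate class is kept unhalved).
fold_count_likelihoods <- function(acl) {
  n2 <- ncol(acl) - 1L                       # 2N
  N <- n2 %/% 2L
  folded <- acl[, 1:(N + 1), drop = FALSE]
  if (N >= 1) {
    upper <- acl[, (n2 + 1):(N + 2), drop = FALSE]  # counts 2N .. N+1
    folded[, 1:N] <- folded[, 1:N] + upper
  }
  folded
}

#' Folded site-frequency-spectrum EM
#'
#' Estimates the proportions of minor-allele count classes `0..N` across
#' sites by EM, treating the per-site folded count likelihoods as mixture
#' component densities. The log-likelihood is non-decreasing over
#' iterations.
#'
#' @param acl Matrix of per-site allele-count likelihoods
#'   (`sites x (2N+1)`, as rows of [allele_count_likelihoods()]), or an
#'   already-folded `sites x (N+1)` matrix with `folded = TRUE`.
#' @param folded Is `acl` already folded?
#' @param tol Convergence tolerance on the SFS proportions (max absolute
#'   change; default 1e-8).
#' @param max_iter Maximum EM iterations.
#' @return An object of class `folded_sfs`: list with `proportions`
#'   (length `N + 1`, summing to 1), `counts` (proportions times number of
#'   sites), `loglik` (trace), `converged`, `n_sites`, `N`.
#' @export
folded_sfs_em <- function(acl, folded = FALSE, tol = 1e-8, max_iter = 1000) {
  K <- if (folded) acl else fold_count_likelihoods(acl)
  if (nrow(K) < 1L) stop("need at least one site", call. = FALSE)
  nc <- ncol(K)
  eta <- rep(1 / nc, nc)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num <- K * rep(eta, each = nrow(K))
    rs <- rowSums(num)
    ll_trace <- c(ll_trace, sum(log(rs)))
    post <- num / rs
    eta_new <- colMeans(post)
    if (max(abs(eta_new - eta)) < tol) {
      eta <- eta_new
      converged <- TRUE
      break
    }
    eta <- eta_new
  }
  structure(list(proportions = eta, counts = eta * nrow(K),
                 loglik = ll_trace, converged = converged,
                 n_sites = nrow(K), N = nc - 1L),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("<folded_sfs> N = %d diploids, %d sites, converged = %s\n",
              x$N, x$n_sites, x$converged))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Nucleotide diversity from count posteriors under an SFS prior
#'
#' Per-site expected heterozygosity is
#' `sum_c P(c | site) c (2N - c) / C(2N, 2)` with the folded SFS as prior
#' over count classes; pi is the sum over sites divided by
#' `total_positions`.
#'
#' @param acl Per-site allele-count likelihood matrix (`sites x (2N+1)`).
#' @param sfs A [folded_sfs_em()] result fitted to the same data.
#' @param total_positions Total interrogated positions (denominator).
#' @param population Label for the report.
#' @param mu Mutation rate for the Ne conversion.
#' @return A `diversity_estimate` (method `"GL-SFS"`).
#' @export
pi_from_sfs <- function(acl, sfs, total_positions, population = "pop",
                        mu = 2.8e-9) {
  K <- fold_count_likelihoods(acl)
  N <- ncol(K) - 1L
  if (N != sfs$N) stop("SFS and count likelihoods disagree on N", call. = FALSE)
  het_term <- (0:N) * (2 * N - (0:N)) / choose(2 * N, 2)
  num <- K * rep(sfs$proportions, each = nrow(K))
  post <- num / rowSums(num)
  site_h <- as.numeric(post %*% het_term)
  if (total_positions < nrow(K)) {
    stop("`total_positions` must be at least the number of sites", call. = FALSE)
  }
  est <- diversity_estimate(population, sum(site_h) / total_positions,
                            S = sum(site_h > 1e-6), total_positions,
                            "GL-SFS", mu)
  est$sfs <- sfs
  est
}

#' Genotype-likelihood nucleotide diversity, end to end
#'
#' Convenience wrapper: computes per-site allele-count likelihoods for one
#' population, fits the folded SFS by EM, and returns pi from the count
#' posteriors.
#'
#' @param gl A [gl_tensor()].
#' @param pm A [popmap()]; `NULL` to use all samples.
#' @param population Population label (`NULL` with `pm = NULL`).
#' @param total_positions Total interrogated positions.
#' @param mu Mutation rate for the Ne conversion.
#' @param ... Passed to [folded_sfs_em()].
#' @return A `diversity_estimate` with the fitted `folded_sfs` attached.
#' @export
pi_gl <- function(gl, pm = NULL, population = NULL,
                  total_positions = n_sites(gl), mu = 2.8e-9, ...) {
  acl <- population_count_likelihoods(gl, pm, population)
  sfs <- folded_sfs_em(acl, ...)
  pi_from_sfs(acl, sfs, total_positions,
              population = population %||% "all", mu = mu)
}
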