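# Pairwise differentiation: per-site Weir & Cockerham (1984) theta from
# genotype counts, Reynolds-style A/B variance components from sample
# allele frequencies with weighted (ratio of sums) and unweighted (mean of
# ratios) averaging, absolute divergence d_XY, and inversion of the
# island-model expectation E(FST) = 1 / (1 + 4 Ne m).

#' Weir-Cockerham per-site F_ST between two populations
#'
#' The two-population, unequal-sample-size Weir & Cockerham (1984)
#' variance-component estimator computed from genotype counts, including
#' the observed-heterozygosity term: per site
#' `theta = a / (a + b + c)`, with `a`, `b`, `c` the among-population,
#' among-individual and within-individual components. The summary is the
#' unweighted mean of per-site theta over sites where `a + b + c > 0`
#' (negative per-site values are retained, matching common practice).
#'
#' @param x A [genotype_matrix()].
#' @param pm A [popmap()].
#' @param pop_a,pop_b Population labels.
#' @return List with `theta` (per site, `NA` where undefined), `mean_fst`
#'   (mean of per-site ratios), `weighted_fst` (ratio of component sums),
#'   `n_sites` (sites entering the summaries), and per-site `a`, `b`, `c`.
#' @export
weir_cockerham_fst <- function(x, pm, pop_a, pop_b) {
  rows_a <- pop_rows(x, pm, pop_a)
  rows_b <- pop_rows(x, pm, pop_b)
  ca <- site_geno_counts(x, rows_a)
  cb <- site_geno_counts(x, rows_b)
  n1 <- rowSums(ca); n2 <- rowSums(cb)
  if (all(n1 == 0)) stop("population has no data: ", pop_a, call. = FALSE)
  if (all(n2 == 0)) stop("population has no data: ", pop_b, call. = FALSE)
  p1 <- (2 * ca[, "n2"] + ca[, "n1"]) / (2 * n1)
  p2 <- (2 * cb[, "n2"] + cb[, "n1"]) / (2 * n2)
  h1 <- ca[, "n1"] / n1
  h2 <- cb[, "n1"] / n2
  comp <- wc_components(unname(n1), unname(n2), unname(p1), unname(p2),
                        unname(h1), unname(h2))
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(is.finite(denom) & denom > 0, comp$a / denom, NA_real_)
  usable <- !is.na(theta)
  list(theta = theta, mean_fst = mean(theta[usable]),
       weighted_fst = sum(comp$a[usable]) / sum(denom[usable]),
       n_sites = sum(usable), a = comp$a, b = comp$b, c = comp$c)
}

# Vectorized WC84 components for r = 2 populations. Sites where either
# population has < 2 genotypes yield NA.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  ok <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c[!ok] <- NA_real_
  list(a = a, b = b, c = c)
}

#' Reynolds-style F_ST components from allele frequencies
#'
#' Per-site between-population (A) and total (B) components computed from
#' sample allele frequencies and sizes with the two-population moment
#' estimator: `A = (p1 - p2)^2 - p1(1-p1)/(2 n1 - 1) - p2(1-p2)/(2 n2 - 1)`
#' (the sampling-bias-corrected squared frequency difference) and
#' `B = p1 (1 - p2) + p2 (1 - p1)` (between-population heterozygosity).
#' The weighted F_ST is `sum(A) / sum(B)` and the unweighted F_ST is the
#' mean of per-site `A / B` over sites with `B > 0`; sites with `B = 0`
#' (monomorphic in both populations for the same allele) contribute
#' nothing to either sum.
#'
#' @param p1,p2 Per-site sample alternate-allele frequencies.
#' @param n1,n2 Per-site diploid sample sizes (scalars recycled).
#' @return An object of class `fst_components`: list with per-site `A`,
#'   `B`, and `weighted_fst`, `unweighted_fst`, `n_sites` (sites with
#'   `B > 0`).
#' @export
reynolds_fst <- function(p1, p2, n1, n2) {
  stopifnot(length(p1) == length(p2))
  n1 <- rep_len(n1, length(p1))
  n2 <- rep_len(n2, length(p2))
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  A <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  B <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- !is.na(A) & !is.na(B)
  pos <- ok & B > 0
  if (!any(ok) || sum(B[ok]) <= 0) {
    stop("no site with positive total component; F_ST undefined", call. = FALSE)
  }
  structure(list(A = A, B = B,
                 weighted_fst = sum(A[ok]) / sum(B[ok]),
                 unweighted_fst = mean(A[pos] / B[pos]),
                 n_sites = sum(pos)),
            class = "fst_components")
}

#' @export
print.fst_components <- function(x, ...) {
  cat(sprintf("<fst_components> weighted = %.4f, unweighted = %.4f (%d sites)\n",
              x$weighted_fst, x$unweighted_fst, x$n_sites))
  invisible(x)
}

#' Absolute divergence d_XY between two populations
#'
#' For biallelic sites with alternate-allele frequencies `x` and `y` in
#' the two populations, `d_XY = x (1 - y) + (1 - x) y`: the probability
#' that one allele drawn from each population differs. The summary is the
#' mean across the supplied SNPs.
#'
#' @param freq_x,freq_y Per-site alternate-allele frequencies in \[0, 1\].
#' @return List with `dxy` per site and `mean_dxy`.
#' @export
dxy <- function(freq_x, freq_y) {
  stopifnot(length(freq_x) == length(freq_y))
  if (any(freq_x < 0 | freq_x > 1 | freq_y < 0 | freq_y > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  d <- freq_x * (1 - freq_y) + (1 - freq_x) * freq_y
  list(dxy = d, mean_dxy = mean(d, na.rm = TRUE))
}

#' Island-model migration rate from F_ST
#'
#' Inverts the equilibrium island-model expectation
#' `E(FST) = 1 / (1 + 4 Ne m)`: the scaled migration rate is
#' `M = 4 Ne m = 1 / FST - 1`, and `m = M / (4 Ne)` given an effective
#' size.
#'
#' @param fst Pairwise F_ST in (0, 1\].
#' @param ne Effective population size used to de-scale `M` into `m`
#'   (`NA` to report `M` only).
#' @return An object of class `migration_estimate`: list with `fst`, `M`,
#'   `m`, `ne_used`, `defined`.
#' @export
migration_from_fst <- function(fst, ne = NA_real_) {
  check_scalar(fst, "fst", upper = 1)
  if (fst <= 0) {
    warning("FST <= 0: migration rate undefined (effectively unbounded)")
    return(structure(list(fst = fst, M = NA_real_, m = NA_real_,
                          ne_used = ne, defined = FALSE),
                     class = "migration_estimate"))
  }
  M <- 1 / fst - 1
  structure(list(fst = fst, M = M,
                 m = if (is.na(ne)) NA_real_ else M / (4 * ne),
                 ne_used = ne, defined = TRUE),
            class = "migration_estimate")
}

#' @export
print.migration_estimate <- function(x, ...) {
  cat(sprintf("<migration_estimate> FST = %.3f -> 4Nem = %.3f, m = %s (Ne = %s)\n",
              x$fst, x$M, format(x$m, digits = 3), format(x$ne_used)))
  invisible(x)
}

#' Metapopulation-level weighted F_ST across all demes
#'
#' The multi-deme fixation index `1 - HS / HT` in ratio-of-sums (weighted)
#' form: per site, `HS` is the mean over demes of the unbiased within-deme
#' expected heterozygosity and `HT` the total expected heterozygosity of
#' the pooled metapopulation (equal deme weights, Nei-Chesser small-sample
#' correction); the summary is `sum(HT - HS) / sum(HT)`. At migration-drift
#' equilibrium in a d-deme island model this estimates
#' `1 / (1 + 4 Ne m (d/(d-1))^2)`, whereas the mean *pairwise* F_ST
#' follows `1 / (1 + 4 Ne m d/(d-1))`.
#'
#' @param x A [genotype_matrix()].
#' @param pm A [popmap()].
#' @return List with `fst` (weighted), `hs`, `ht` (per-site vectors), and
#'   `n_sites` (sites with positive `HT` entering the sums).
#' @export
global_fst <- function(x, pm) {
  labels <- align_popmap(x, pm)
  pops <- unique(labels)
  if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
  d <- length(pops)
  freqs <- vapply(pops, function(p) site_alt_freq(x, which(labels == p)),
                  numeric(n_sites(x)))
  ns <- vapply(pops, function(p) {
    colSums(!is.na(x$dosage[labels == p, , drop = FALSE]))
  }, numeric(n_sites(x)))
  hs_mat <- (2 * ns / (2 * ns - 1)) * 2 * freqs * (1 - freqs)
  hs <- rowMeans(hs_mat)
  pbar <- rowMeans(freqs)
  ht <- 2 * pbar * (1 - pbar) + hs / (2 * mean(ns) * d)
  ok <- is.finite(hs) & is.finite(ht) & ht > 0
  if (!any(ok)) stop("no usable site for global F_ST", call. = FALSE)
  list(fst = sum(ht[ok] - hs[ok]) / sum(ht[ok]), hs = hs, ht = ht,
       n_sites = sum(ok))
}

#' Pairwise differentiation table
#'
#' Computes, for every pair of populations, the Reynolds-style weighted
#' and unweighted F_ST, Weir-Cockerham mean theta, and mean d_XY, over
#' the sites at which both populations have at least `min_diploids`
#' genotyped individuals.
#'
#' @param x A [genotype_matrix()].
#' @param pm A [popmap()].
#' @param pairs Optional 2-column character matrix of pairs; default all
#'   unordered pairs of populations in `pm`.
#' @param min_diploids Per-population minimum genotyped individuals for a
#'   site to enter a pair's statistics (default 2).
#' @return Data frame with columns `pop_a`, `pop_b`, `weighted_fst`,
#'   `unweighted_fst`, `wc_fst`, `dxy`, `n_sites`.
#' @export
pairwise_stats <- function(x, pm, pairs = NULL, min_diploids = 2) {
  pops <- unique(align_popmap(x, pm))
  if (is.null(pairs)) {
    if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
    pairs <- t(utils::combn(pops, 2))
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pa <- pairs[i, 1]; pb <- pairs[i, 2]
    rows_a <- pop_rows(x, pm, pa)
    rows_b <- pop_rows(x, pm, pb)
    na <- colSums(!is.na(x$dosage[rows_a, , drop = FALSE]))
    nb <- colSums(!is.na(x$dosage[rows_b, , drop = FALSE]))
    keep <- na >= min_diploids & nb >= min_diploids
    xs <- x[, keep]
    p1 <- site_alt_freq(xs, rows_a)
    p2 <- site_alt_freq(xs, rows_b)
    rey <- reynolds_fst(p1, p2, na[keep], nb[keep])
    wc <- weir_cockerham_fst(xs, pm, pa, pb)
    dx <- dxy(p1, p2)
    out[[i]] <- data.frame(pop_a = pa, pop_b = pb,
                           weighted_fst = rey$weighted_fst,
                           unweighted_fst = rey$unweighted_fst,
                           wc_fst = wc$mean_fst, dxy = dx$mean_dxy,
                           n_sites = sum(keep), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
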