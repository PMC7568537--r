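#' Genotype-likelihood tensor
#'
#' Per sample x site likelihoods of the three diploid genotypes at a
#' biallelic site (hom-ref, het, hom-alt). Values are stored internally as
#' natural-log likelihoods; they need not be normalized across genotypes.
#' An entry is missing when no reads were observed, in which case all three
#' log-likelihoods are `-Inf` and the missing mask is set.
#'
#' @param loglik Numeric array `samples x sites x 3` of natural-log
#'   genotype likelihoods.
#' @param sites Site table as for [genotype_matrix()].
#' @param samples Sample identifiers; default `S1..Sn`.
#' @param missing Optional logical `samples x sites` mask; by default an
#'   entry is missing when all three log-likelihoods are non-finite.
#'
#' @return An object of class `gl_tensor` with elements `samples`, `sites`,
#'   `loglik`, `missing`.
#' @export
gl_tensor <- function(loglik, sites = NULL, samples = NULL, missing = NULL) {
  if (!is.array(loglik) || length(dim(loglik)) != 3L || dim(loglik)[3] != 3L) {
    stop("`loglik` must be a samples x sites x 3 array", call. = FALSE)
  }
  n <- dim(loglik)[1]
  m <- dim(loglik)[2]
  if (is.null(samples)) samples <- dimnames(loglik)[[1]] %||% paste0("S", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n) stop("`samples` length must match dim(loglik)[1]", call. = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(chrom = rep("chr1", m), pos = seq_len(m),
                        ref = rep("A", m), alt = rep("T", m),
                        stringsAsFactors = FALSE)
  }
  sites <- validate_sites(sites, m)
  if (is.null(missing)) {
    missing <- apply(loglik, c(1, 2), function(v) all(!is.finite(v)))
    if (m == 0L || n == 0L) missing <- matrix(logical(0), n, m)
  }
  missing <- matrix(as.logical(missing), n, m)
  # a non-missing entry must carry some likelihood mass
  ok <- missing | apply(is.finite(loglik), c(1, 2), any)
  if (n > 0 && m > 0 && !all(ok)) {
    stop("non-missing genotype-likelihood triple with no finite value", call. = FALSE)
  }
  dimnames(loglik) <- list(samples, NULL, c("hom_ref", "het", "hom_alt"))
  structure(list(samples = samples, sites = sites, loglik = loglik, missing = missing),
            class = "gl_tensor")
}

#' @export
print.gl_tensor <- function(x, ...) {
  cat(sprintf("<gl_tensor> %d samples x %d sites (%.1f%% missing)\n",
              n_samples(x), n_sites(x), 100 * mean(x$missing)))
  invisible(x)
}

#' Subset a genotype-likelihood tensor by site
#'
#' @param x A `gl_tensor`.
#' @param j Site index (integer or logical).
#' @return A `gl_tensor` restricted to the selected sites.
#' @export
subset_gl_sites <- function(x, j) {
  gl_tensor(x$loglik[, j, , drop = FALSE],
            sites = x$sites[j, , drop = FALSE],
            samples = x$samples,
            missing = x$missing[, j, drop = FALSE])
}

# Linear-scale likelihoods for one site, rows = samples, cols = 3 genotypes,
# rescaled so each non-missing row has max 1. Missing rows are NA.
site_linear_gl <- function(x, j) {
  ll <- x$loglik[, j, , drop = TRUE]
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  mx <- apply(ll, 1, max)
  out <- exp(ll - mx)
  out[!is.finite(mx), ] <- NA_real_
  out[x$missing[, j], ] <- NA_real_
  out
}
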