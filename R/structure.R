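# Population delineation: single-allele-sampling IBS distances,
# hierarchical clustering with Newick export, classical (Torgerson) MDS,
# and BIC selection of the number of Gaussian mixture components on the
# MDS embedding.

#' Identity-by-state distance matrix with single-allele sampling
#'
#' For every sample and site, one allele is sampled uniformly from the
#' genotype (dosage g yields the alternate allele with probability g/2),
#' emulating single-read IBS sampling. The distance between samples i and
#' j is the fraction of mismatching sampled alleles over the M sites where
#' both have data: `d_ij = sum_m (1 - I(b_i = b_j)) / M`. Sites with
#' full-sample minor allele frequency below `min_maf` are excluded first.
#'
#' @param x A [genotype_matrix()].
#' @param min_maf Minor-allele-frequency floor on the full-sample
#'   frequency (default 0.01).
#' @param seed Integer seed for the allele sampling.
#' @return An object of class `ibs_dist`: list with `samples`, `d`
#'   (symmetric matrix, zero diagonal, `NA` where a pair shares no sites)
#'   and `n_shared_sites` (pairwise M).
#' @export
ibs_distance_matrix <- function(x, min_maf = 0.01, seed = 1) {
  if (n_samples(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  p <- site_alt_freq(x)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf
  d0 <- x$dosage[, keep, drop = FALSE]
  n <- nrow(d0)
  allele <- with_seed(seed, {
    u <- matrix(runif(length(d0)), nrow = n)
    a <- (u < d0 / 2) * 1L
    a[is.na(d0)] <- NA_integer_
    a
  })
  obs <- !is.na(allele)
  shared <- obs %*% t(obs)                       # pairwise M
  a0 <- allele; a0[!obs] <- 0L
  alt <- a0 * obs                                # sampled alt, observed only
  ref <- (1 - a0) * obs                          # sampled ref, observed only
  mism <- alt %*% t(ref) + ref %*% t(alt)
  d <- ifelse(shared > 0, mism / shared, NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(x$samples, x$samples)
  structure(list(samples = x$samples, d = d, n_shared_sites = shared,
                 n_sites_used = sum(keep), seed = as.integer(seed)),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("<ibs_dist> %d samples over %d sites; mean d = %.3f\n",
              length(x$samples), x$n_sites_used,
              mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Hierarchical clustering of an IBS distance matrix
#'
#' Agglomerative clustering (average linkage by default) of the pairwise
#' distances, with the dendrogram also rendered as a Newick string via
#' \pkg{ape}.
#'
#' @param D An `ibs_dist` or a symmetric numeric matrix.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return List with `hclust` (the tree), `newick` (character), and
#'   `linkage`.
#' @export
hierarchical_cluster <- function(D, linkage = "average") {
  d <- if (inherits(D, "ibs_dist")) D$d else as.matrix(D)
  if (anyNA(d)) {
    stop("undefined pairwise distances (no shared sites); filter more strictly",
         call. = FALSE)
  }
  hc <- hclust(as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy), linkage = linkage)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric MDS via eigendecomposition of the double-centered squared
#' distance matrix; axes are ordered by decreasing eigenvalue and
#' negative-eigenvalue axes are dropped.
#'
#' @param D An `ibs_dist` or symmetric matrix.
#' @param n_axes Number of axes requested (default 3); truncated with a
#'   warning if fewer positive eigenvalues exist.
#' @return List with `coords` (samples x axes), `eigenvalues` (all, in
#'   decreasing order), and `n_axes`.
#' @export
classical_mds <- function(D, n_axes = 3) {
  d <- if (inherits(D, "ibs_dist")) D$d else as.matrix(D)
  if (anyNA(d)) stop("undefined pairwise distances", call. = FALSE)
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  k <- min(n_axes, pos)
  if (k < n_axes) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes", pos, k))
  }
  coords <- if (k > 0) fit$points[, seq_len(k), drop = FALSE] else
    matrix(0, n, n_axes, dimnames = list(rownames(d), NULL))
  list(coords = coords, eigenvalues = eig, n_axes = ncol(coords))
}

#' Select the number of clusters by BIC on MDS coordinates
#'
#' Fits Gaussian mixtures with a shared diagonal covariance (model
#' \code{"EEI"}, or \code{"E"} for 1-axis data) for each candidate K using
#' \pkg{mclust}, and reports BIC in the minimizing convention
#' `-2 loglik + npar log(n)` (the negative of mclust's convention); the
#' selected K minimizes it. Candidates with K >= n_samples are skipped.
#'
#' @param coords Numeric matrix of embedding coordinates (samples x axes),
#'   e.g. from [classical_mds()].
#' @param k_range Candidate K values (default 1:8).
#' @param seed Seed (mclust's initialization here is deterministic; the
#'   seed is recorded for provenance).
#' @return An object of class `k_selection`: data frame `table` with
#'   columns `k` and `bic`, plus `selected_k`.
#' @export
select_k_bic <- function(coords, k_range = 1:8, seed = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  drop_k <- k_range >= n
  if (any(drop_k)) {
    warning("skipping K >= number of samples: ",
            paste(k_range[drop_k], collapse = ", "))
    k_range <- k_range[!drop_k]
  }
  if (!length(k_range)) stop("no feasible K in `k_range`", call. = FALSE)
  model <- if (ncol(coords) == 1L) "E" else "EEI"
  bic <- vapply(k_range, function(k) {
    fit <- with_seed(seed, suppressWarnings(
      mclust::mclustBIC(coords, G = k, modelNames = model, verbose = FALSE)))
    v <- suppressWarnings(max(fit[, model], na.rm = TRUE))
    if (!is.finite(v)) NA_real_ else -v        # minimizing convention
  }, 0)
  tab <- data.frame(k = k_range, bic = bic)
  sel <- tab$k[which.min(tab$bic)]
  structure(list(table = tab, selected_k = sel, model = model),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> model %s, selected K = %d\n", x$model, x$selected_k))
  print(x$table, row.names = FALSE)
  invisible(x)
}
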