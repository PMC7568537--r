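#' Admixture ancestry estimation by EM
#'
#' Maximum-likelihood estimation of the admixture model in which
#' individual i's alternate-allele dosage at site j is
#' `Binomial(2, sum_k q_ik f_kj)`: Q holds each individual's ancestry
#' proportions from K source populations and F the source allele
#' frequencies. With a [genotype_matrix()] the dosages enter directly
#' (missing genotypes are marginalized out); with a [gl_tensor()] the
#' three genotypes are posterior-weighted each iteration, as in
#' NGSadmix-style analyses. EM is run from `n_restarts` random starts
#' (Dirichlet(1) rows for Q) and the best final log-likelihood is kept.
#'
#' @param x A [genotype_matrix()] or [gl_tensor()].
#' @param K Number of ancestral populations (>= 1).
#' @param seed Integer seed governing all restarts.
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param n_restarts Number of random restarts (default 5).
#' @return An object of class `admixture_result`: list with `K`, `Q`
#'   (individuals x K, rows summing to 1), `F` (K x sites),
#'   `log_likelihood`, `ll_trace` (best restart), `n_iterations`,
#'   `converged`, `seed`.
#' @export
admixture_em <- function(x, K, seed = 1, tol = 1e-6, max_iter = 2000,
                         n_restarts = 5) {
  check_scalar(K, "K", lower = 1, integer = TRUE)
  check_scalar(n_restarts, "n_restarts", lower = 1, integer = TRUE)
  gl_mode <- inherits(x, "gl_tensor")
  if (!gl_mode && !inherits(x, "genotype_matrix")) {
    stop("`x` must be a genotype_matrix or gl_tensor", call. = FALSE)
  }
  I <- n_samples(x); J <- n_sites(x)
  if (K > I) stop("K cannot exceed the number of individuals", call. = FALSE)

  if (gl_mode) {
    L <- vapply(seq_len(J), function(j) site_linear_gl(x, j), matrix(0, I, 3))
    L0 <- matrix(L[, 1, ], I, J)
    L1 <- matrix(L[, 2, ], I, J)
    L2 <- matrix(L[, 3, ], I, J)
    L0[is.na(L0)] <- 1; L1[is.na(L1)] <- 1; L2[is.na(L2)] <- 1
    p_overall <- colMeans((L1 + 2 * L2) / (L0 + L1 + L2)) / 2
    G <- NULL
  } else {
    G <- x$dosage
    L0 <- L1 <- L2 <- NULL
    p_overall <- site_alt_freq(x)
    p_overall[is.na(p_overall)] <- 0.5
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L, {
      Q <- matrix(-log(runif(I * K)), I, K)
      Q <- Q / rowSums(Q)
      Fm <- matrix(pmin(pmax(rep(p_overall, each = K) +
                               runif(K * J, -0.2, 0.2), 0.01), 0.99), K, J)
      admixture_em_run(G, L0, L1, L2, Q, Fm, gl_mode, tol, max_iter)
    })
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  structure(list(K = as.integer(K), Q = best$Q, F = best$F,
                 log_likelihood = best$log_likelihood,
                 ll_trace = best$ll_trace, n_iterations = best$n_iterations,
                 converged = best$converged, seed = as.integer(seed),
                 samples = x$samples),
            class = "admixture_result")
}

admixture_em_run <- function(G, L0, L1, L2, Q, Fm, gl_mode, tol, max_iter) {
  eps <- 1e-9
  if (!gl_mode) {
    obs <- !is.na(G)
    Gs <- G; Gs[!obs] <- 0L
  }
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- pmin(pmax(Q %*% Fm, eps), 1 - eps)
    if (gl_mode) {
      W0 <- L0 * (1 - P)^2
      W1 <- L1 * 2 * P * (1 - P)
      W2 <- L2 * P^2
      S <- W0 + W1 + W2
      ll <- sum(log(S))
      Ge <- (W1 + 2 * W2) / S
      A <- Ge / P
      B <- (2 - Ge) / (1 - P)
    } else {
      ll <- sum((Gs * log(P) + (2 - Gs) * log(1 - P))[obs])
      A <- Gs / P
      B <- (2 - Gs) / (1 - P)
      A[!obs] <- 0
      B[!obs] <- 0
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    U <- crossprod(A, Q) * t(Fm)            # J x K expected alt from k
    V <- crossprod(B, Q) * t(1 - Fm)
    Fm <- t(U / pmax(U + V, 1e-300))
    Fm <- pmin(pmax(Fm, eps), 1 - eps)
    Qn <- Q * (A %*% t(Fm) + B %*% t(1 - Fm))
    Q <- Qn / rowSums(Qn)
  }
  list(Q = Q, F = Fm, log_likelihood = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iterations = length(ll_trace),
       converged = converged)
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("<admixture_result> K = %d, %d individuals, loglik = %.2f (%s in %d iters)\n",
              x$K, nrow(x$Q), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Mean ancestry assigned to each individual's own population
#'
#' Resolves label switching by greedily matching each population to the
#' mixture component with the largest mean ancestry among its members,
#' then reports, per individual, the ancestry proportion assigned to the
#' component matched to its own population.
#'
#' @param res An [admixture_em()] result.
#' @param pm A [popmap()] covering the samples.
#' @return Named numeric vector (one entry per individual) of own-deme
#'   ancestry proportions.
#' @export
own_deme_ancestry <- function(res, pm) {
  labels <- pm$population[match(res$samples, pm$sample)]
  if (anyNA(labels)) stop("samples missing from population map", call. = FALSE)
  pops <- unique(labels)
  means <- do.call(rbind, lapply(pops, function(p) {
    colMeans(res$Q[labels == p, , drop = FALSE])
  }))
  rownames(means) <- pops
  assign <- rep(NA_integer_, length(pops))
  names(assign) <- pops
  avail <- seq_len(res$K)
  for (p in pops[order(-apply(means, 1, max))]) {
    k <- avail[which.max(means[p, avail])]
    assign[p] <- k
    avail <- setdiff(avail, k)
    if (!length(avail)) avail <- seq_len(res$K)   # more pops than K
  }
  setNames(res$Q[cbind(seq_along(labels), assign[labels])], res$samples)
}
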