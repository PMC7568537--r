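# Two filtering tracks. Hard-call track: per-genotype depth masking, then
# site rules biallelic-SNV -> call-rate -> singleton -> excess-het, with
# removal attributed to the first failing rule. GL track: sample
# representation -> SNP likelihood-ratio -> heterozygote-majority paralog
# screen. The rule order is fixed; it cannot change the retained set, only
# how removals are attributed in the report.

#' Hard-call filter parameters
#'
#' @param min_genotype_depth Genotypes with read depth below this are set
#'   missing before any site-level rule (default 2; 0 disables).
#' @param require_biallelic_snv Drop indels, multi-allelic and non-diploid
#'   records (default `TRUE`).
#' @param drop_singletons Drop sites whose minor allele occurs exactly
#'   once across all non-missing genotypes (default `TRUE`).
#' @param min_call_rate Minimum fraction of samples genotyped (default 0.75).
#' @param excess_het_p_threshold Sites with one-sided exact
#'   heterozygote-excess p below this are dropped as likely paralogs
#'   (default 0.1).
#' @return An object of class `hard_filter_params`.
#' @export
hard_filter_params <- function(min_genotype_depth = 2,
                               require_biallelic_snv = TRUE,
                               drop_singletons = TRUE,
                               min_call_rate = 0.75,
                               excess_het_p_threshold = 0.1) {
  check_scalar(min_genotype_depth, "min_genotype_depth", lower = 0, integer = TRUE)
  check_scalar(min_call_rate, "min_call_rate", lower = 0, upper = 1)
  check_scalar(excess_het_p_threshold, "excess_het_p_threshold", lower = 0, upper = 1)
  structure(list(min_genotype_depth = as.integer(min_genotype_depth),
                 require_biallelic_snv = isTRUE(require_biallelic_snv),
                 drop_singletons = isTRUE(drop_singletons),
                 min_call_rate = min_call_rate,
                 excess_het_p_threshold = excess_het_p_threshold),
            class = "hard_filter_params")
}

new_filter_report <- function(n_input, rules, removed) {
  report <- data.frame(rule = rules, removed = removed,
                       stringsAsFactors = FALSE)
  structure(list(n_input = n_input, rules = report,
                 n_retained = n_input - sum(removed)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d sites in, %d retained\n", x$n_input, x$n_retained))
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  %-18s -%d\n", x$rules$rule[i], x$rules$removed[i]))
  }
  invisible(x)
}

#' Filter hard genotype calls
#'
#' Applies the hard-call track: low-depth genotypes are masked to missing,
#' then sites are removed in order by the biallelic-SNV, call-rate,
#' singleton, and heterozygote-excess rules. Each removed site is counted
#' against the first rule it fails, so the report's removals plus retained
#' sites always sum to the input count.
#'
#' @param x A [genotype_matrix()].
#' @param params A [hard_filter_params()].
#' @return List with `matrix` (filtered [genotype_matrix()]) and `report`
#'   (a `filter_report`).
#' @export
filter_hard_calls <- function(x, params = hard_filter_params()) {
  if (params$min_genotype_depth > 0L) {
    if (is.null(x$depth)) {
      stop("depth filtering requested but `x` carries no depth", call. = FALSE)
    }
    mask <- is.na(x$depth) | x$depth < params$min_genotype_depth
    x$dosage[mask] <- NA_integer_
  }
  m <- n_sites(x)
  alive <- rep(TRUE, m)
  removed <- integer(4)

  if (params$require_biallelic_snv) {
    bad <- x$sites$is_multiallelic | x$sites$is_indel |
      (x$sites$is_nondiploid %||% rep(FALSE, m))
    removed[1] <- sum(alive & bad)
    alive <- alive & !bad
  }

  call_rate <- colMeans(!is.na(x$dosage))
  bad <- call_rate < params$min_call_rate
  removed[2] <- sum(alive & bad)
  alive <- alive & !bad

  if (params$drop_singletons) {
    ac <- colSums(x$dosage, na.rm = TRUE)
    an <- 2L * colSums(!is.na(x$dosage))
    mac <- pmin(ac, an - ac)
    bad <- mac == 1L
    removed[3] <- sum(alive & bad)
    alive <- alive & !bad
  }

  if (params$excess_het_p_threshold > 0) {
    counts <- site_geno_counts(x)
    idx <- which(alive)
    p <- hwe_excess_het_p(counts[idx, "n0"], counts[idx, "n1"], counts[idx, "n2"])
    bad_idx <- idx[p < params$excess_het_p_threshold]
    removed[4] <- length(bad_idx)
    alive[bad_idx] <- FALSE
  }

  report <- new_filter_report(m, c("biallelic_snv", "call_rate", "singleton",
                                   "excess_het"), removed)
  if (report$n_retained == 0L) warning("all sites removed by hard-call filters")
  list(matrix = x[, alive], report = report)
}

#' Exact Hardy-Weinberg heterozygote-excess p-value
#'
#' One-sided exact test for an excess of heterozygotes: the probability,
#' conditional on the observed allele counts, of at least the observed
#' number of heterozygotes under Hardy-Weinberg equilibrium
#' (the heterozygote-excess tail of the Wigginton-style exact HWE
#' distribution). A heterozygote excess at a RAD locus is the signature of
#' paralogous tags collapsed into one locus.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectors recycled
#'   together); each triple must sum to at least 1.
#' @return p-values in \[0, 1\]; monomorphic sites give 1.
#' @export
hwe_excess_het_p <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  mapply(function(n0, n1, n2) {
    n <- n0 + n1 + n2
    if (n < 1) stop("genotype counts must sum to at least 1", call. = FALSE)
    na <- min(2 * n0 + n1, 2 * n2 + n1)      # minor-allele copies
    if (na == 0) return(1)
    ks <- seq(na %% 2, na, by = 2)           # feasible heterozygote counts
    # P(k hets | n, na) proportional to n! 2^k / (k! n_hom_min! n_hom_maj!)
    logw <- ks * log(2) - lgamma(ks + 1) - lgamma((na - ks) / 2 + 1) -
      lgamma(n - ks - (na - ks) / 2 + 1)
    w <- exp(logw - max(logw))
    sum(w[ks >= n1]) / sum(w)
  }, n_hom_ref, n_het, n_hom_alt)
}

#' Genotype-likelihood filter parameters
#'
#' @param min_sample_fraction Minimum fraction of samples with data at a
#'   site (default 0.8).
#' @param snp_p_threshold Sites whose SNP likelihood-ratio p-value
#'   ([gl_snp_test()]) is at or above this are dropped as non-variable
#'   (default 0.05).
#' @param het_majority_threshold Sites whose mean posterior heterozygote
#'   fraction (uniform genotype prior) exceeds this are dropped as likely
#'   paralogs (default 0.5).
#' @param min_maf_for_ibs Minor-allele-frequency floor used later by the
#'   IBS distance stage (default 0.01; stored here because it belongs to
#'   the same screening step).
#' @return An object of class `gl_filter_params`.
#' @export
gl_filter_params <- function(min_sample_fraction = 0.8,
                             snp_p_threshold = 0.05,
                             het_majority_threshold = 0.5,
                             min_maf_for_ibs = 0.01) {
  check_scalar(min_sample_fraction, "min_sample_fraction", lower = 0, upper = 1)
  check_scalar(snp_p_threshold, "snp_p_threshold", lower = 0, upper = 1)
  check_scalar(het_majority_threshold, "het_majority_threshold", lower = 0, upper = 1)
  check_scalar(min_maf_for_ibs, "min_maf_for_ibs", lower = 0, upper = 0.5)
  structure(list(min_sample_fraction = min_sample_fraction,
                 snp_p_threshold = snp_p_threshold,
                 het_majority_threshold = het_majority_threshold,
                 min_maf_for_ibs = min_maf_for_ibs),
            class = "gl_filter_params")
}

#' Filter sites on the genotype-likelihood track
#'
#' Applies, in order: the sample-representation rule (fraction of
#' non-missing samples below `min_sample_fraction`), the SNP
#' likelihood-ratio rule (sites not significantly polymorphic), and the
#' heterozygote-majority paralog rule (mean posterior heterozygote
#' fraction under a uniform genotype prior above
#' `het_majority_threshold`). Attribution is to the first failing rule.
#'
#' @param x A [gl_tensor()].
#' @param params A [gl_filter_params()].
#' @return List with `tensor` (filtered [gl_tensor()]) and `report`.
#' @export
filter_gl_sites <- function(x, params = gl_filter_params()) {
  m <- n_sites(x)
  alive <- rep(TRUE, m)
  removed <- integer(3)

  frac <- colMeans(!x$missing)
  bad <- frac < params$min_sample_fraction
  removed[1] <- sum(alive & bad)
  alive <- alive & !bad

  het_post <- numeric(m)
  snp_p <- rep(1, m)
  for (j in which(alive)) {
    lin <- site_linear_gl(x, j)
    snp_p[j] <- gl_snp_test(lin)$p_value
    norm <- lin / rowSums(lin)
    het_post[j] <- mean(norm[, 2], na.rm = TRUE)
  }
  bad <- snp_p >= params$snp_p_threshold
  removed[2] <- sum(alive & bad)
  alive <- alive & !bad

  bad <- het_post > params$het_majority_threshold
  removed[3] <- sum(alive & bad)
  alive <- alive & !bad

  report <- new_filter_report(m, c("representation", "snp_lrt", "het_majority"),
                              removed)
  if (report$n_retained == 0L) warning("all sites removed by GL filters")
  list(tensor = subset_gl_sites(x, alive), report = report)
}
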