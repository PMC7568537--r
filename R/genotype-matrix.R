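#' Genotype dosage matrix
#'
#' The central hard-call container: alternate-allele dosage (0, 1, 2 or `NA`
#' for missing) for every sample at every biallelic site, with optional
#' per-genotype read depth. Samples are rows, sites are columns, mirroring
#' the individuals-by-loci orientation of most population-genetic software.
#'
#' @param dosage Integer matrix (samples x sites) with entries in
#'   `{0, 1, 2, NA}`.
#' @param sites Data frame describing sites, one row per column of `dosage`,
#'   with columns `chrom`, `pos` (1-based), `ref`, `alt`, and optionally
#'   `is_indel` and `is_multiallelic` flags (default `FALSE`). If `NULL`,
#'   a placeholder site table on a single contig is created.
#' @param depth Optional integer matrix of read depths, same shape as
#'   `dosage`; `NA` where no reads were observed.
#' @param samples Character vector of sample identifiers; defaults to the
#'   row names of `dosage` or `S1..Sn`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `sites`, `dosage`, `depth`.
#' @export
genotype_matrix <- function(dosage, sites = NULL, depth = NULL, samples = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("`dosage` entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(samples)) samples <- rownames(dosage) %||% paste0("S", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n) stop("`samples` length must match nrow(dosage)", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample identifiers", call. = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(chrom = rep("chr1", m), pos = seq_len(m),
                        ref = rep("A", m), alt = rep("T", m),
                        stringsAsFactors = FALSE)
  }
  sites <- validate_sites(sites, m)
  if (!is.null(depth)) {
    if (!is.matrix(depth)) depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(dosage))) {
      stop("`depth` must have the same dimensions as `dosage`", call. = FALSE)
    }
    if (any(depth[!is.na(depth)] < 0L)) stop("`depth` must be non-negative", call. = FALSE)
    dimnames(depth) <- list(samples, NULL)
  }
  dimnames(dosage) <- list(samples, NULL)
  structure(list(samples = samples, sites = sites, dosage = dosage, depth = depth),
            class = "genotype_matrix")
}

validate_sites <- function(sites, m) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("`sites` missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(sites) != m) stop("`sites` must have one row per site column", call. = FALSE)
  if (any(sites$pos < 1)) stop("site `pos` must be >= 1 (1-based)", call. = FALSE)
  if (is.null(sites$is_indel)) {
    sites$is_indel <- nchar(sites$ref) != 1L | nchar(sites$alt) != 1L
  }
  if (is.null(sites$is_multiallelic)) sites$is_multiallelic <- rep(FALSE, m)
  snv <- !sites$is_multiallelic & !sites$is_indel
  if (any(snv & sites$ref == sites$alt)) {
    stop("site with identical ref and alt allele", call. = FALSE)
  }
  rownames(sites) <- NULL
  sites
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%.1f%% missing%s)\n",
              n_samples(x), n_sites(x),
              100 * mean(is.na(x$dosage)),
              if (is.null(x$depth)) ", no depth" else ", with depth"))
  invisible(x)
}

#' Numbers of samples and sites
#'
#' @param x A `genotype_matrix` or `gl_tensor`.
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (integer, logical or character).
#' @param j Site index (integer or logical).
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected samples and sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(n_sites(x))
  if (is.character(i)) i <- match(i, x$samples)
  if (anyNA(i)) stop("unknown sample in subset", call. = FALSE)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  sites = x$sites[j, , drop = FALSE],
                  depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
                  samples = x$samples[i])
}

# Alternate-allele frequency across all non-missing genotypes, per site.
site_alt_freq <- function(x, rows = NULL) {
  d <- if (is.null(rows)) x$dosage else x$dosage[rows, , drop = FALSE]
  called <- colSums(!is.na(d))
  ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
}

# Genotype counts (hom-ref, het, hom-alt) per site over given rows.
site_geno_counts <- function(x, rows = NULL) {
  d <- if (is.null(rows)) x$dosage else x$dosage[rows, , drop = FALSE]
  cbind(n0 = colSums(d == 0L, na.rm = TRUE),
        n1 = colSums(d == 1L, na.rm = TRUE),
        n2 = colSums(d == 2L, na.rm = TRUE))
}
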