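# BEAGLE genotype-likelihood text interchange: one row per marker, columns
# marker, allele1, allele2, then three linear-scale likelihood columns
# (hom-ref, het, hom-alt) per individual. Alleles are 0/1/2/3-coded for
# A/C/G/T. Per the format's convention, rows are rescaled so each
# individual's maximum likelihood is 1; an all-zero triple means missing.

BEAGLE_BASES <- c("A", "C", "G", "T")

encode_allele <- function(a) {
  i <- match(a, BEAGLE_BASES)
  ifelse(is.na(i), a, as.character(i - 1L))
}

decode_allele <- function(a) {
  ifelse(a %in% c("0", "1", "2", "3"), BEAGLE_BASES[as.integer(a) + 1L], a)
}

#' Write genotype likelihoods in BEAGLE text format
#'
#' @param x A [gl_tensor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beagle_gl <- function(x, path) {
  n <- n_samples(x)
  m <- n_sites(x)
  marker <- paste(x$sites$chrom, x$sites$pos, sep = "_")
  header <- c("marker", "allele1", "allele2", rep(x$samples, each = 3))
  lines <- character(m)
  for (j in seq_len(m)) {
    lin <- site_linear_gl(x, j)             # n x 3, row max 1, NA if missing
    lin[is.na(lin)] <- 0
    vals <- formatC(as.vector(t(lin)), format = "g", digits = 6)
    lines[j] <- paste(c(marker[j],
                        encode_allele(x$sites$ref[j]),
                        encode_allele(x$sites$alt[j]), vals), collapse = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a BEAGLE genotype-likelihood text file
#'
#' @param path Path to the file (tab- or space-separated, with header).
#' @return A [gl_tensor()]; likelihood triples that are all zero are
#'   marked missing.
#' @export
read_beagle_gl <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "")
  if (nrow(raw) < 1L) stop("empty BEAGLE file: ", path, call. = FALSE)
  header <- unlist(raw[1, ], use.names = FALSE)
  body <- raw[-1, , drop = FALSE]
  k <- ncol(raw) - 3L
  if (k < 3L || k %% 3L != 0L) {
    stop("BEAGLE file must have 3 likelihood columns per individual after ",
         "marker/allele1/allele2; found ", k, " value columns", call. = FALSE)
  }
  n <- k %/% 3L
  samples <- header[seq(4L, by = 3L, length.out = n)]
  if (anyDuplicated(samples)) samples <- paste0("Ind", seq_len(n) - 1L)

  marker <- body[[1]]
  us <- regexpr("_[^_]*$", marker)
  if (any(us < 0)) stop("BEAGLE marker names must be chrom_pos", call. = FALSE)
  chrom <- substr(marker, 1L, us - 1L)
  pos <- suppressWarnings(as.integer(substring(marker, us + 1L)))
  if (anyNA(pos)) stop("non-numeric position in BEAGLE marker name", call. = FALSE)

  vals <- vapply(body[, -(1:3), drop = FALSE],
                 function(col) as.numeric(col), numeric(nrow(body)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(body))
  if (anyNA(vals) || any(vals < 0)) {
    stop("BEAGLE likelihoods must be non-negative numbers", call. = FALSE)
  }
  m <- nrow(body)
  ll <- array(-Inf, dim = c(n, m, 3))
  for (i in seq_len(n)) {
    block <- vals[, (3 * i - 2):(3 * i), drop = FALSE]  # m x 3
    block[rowSums(block) == 0, ] <- NA                  # missing
    ll[i, , ] <- log(block)
  }
  ll[is.na(ll)] <- -Inf
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = decode_allele(body[[2]]),
                      alt = decode_allele(body[[3]]),
                      stringsAsFactors = FALSE)
  gl_tensor(ll, sites = sites, samples = samples)
}
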