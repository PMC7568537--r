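#' Read a diploid biallelic-SNP VCF into a genotype matrix
#'
#' Parses the GT (and, when present, DP) fields of a VCF v4.2 file.
#' Diploid genotypes are converted to alternate-allele dosage
#' (`0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`); phased
#' separators (`|`) are accepted. Records with more than one ALT allele,
#' indel alleles, or non-diploid GT fields are retained with their
#' `is_multiallelic` / `is_indel` / `is_nondiploid` site flags set and
#' dosage marked missing, so the filtering stage can account for them
#' rather than losing them silently.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @return A [genotype_matrix()]; the depth slot is `NULL` when the file
#'   carries no DP field.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  validate_vcf_columns(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  m <- nrow(fix)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  alt[is.na(alt)] <- "."
  is_multi <- grepl(",", alt, fixed = TRUE)
  alt1 <- vapply(strsplit(alt, ",", fixed = TRUE), `[`, "", 1L)
  is_indel <- nchar(ref) != 1L | (nchar(alt1) != 1L & !is_multi) | alt1 == "."
  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos)) {
    stop("malformed VCF: non-numeric POS at record ",
         which(is.na(pos))[1], call. = FALSE)
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF carries no GT field", call. = FALSE)
  samples <- colnames(gt)
  gt <- t(gt)                               # samples x sites
  gtc <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gtc), ncol(gtc))
  dosage[gtc == "0/0"] <- 0L
  dosage[gtc == "0/1" | gtc == "1/0"] <- 1L
  dosage[gtc == "1/1"] <- 2L
  # tokens with no separator and not "." are haploid calls
  is_nondiploid <- apply(gtc, 2, function(col) {
    any(!is.na(col) & col != "." & !grepl("/", col, fixed = TRUE))
  })
  unknown <- !is.na(gtc) & gtc != "." & grepl("/", gtc, fixed = TRUE) &
    is.na(dosage) & gtc != "./."
  flagged <- is_multi | is_indel | is_nondiploid
  if (any(unknown[, !flagged, drop = FALSE])) {
    j <- which(colSums(unknown) > 0 & !flagged)[1]
    stop("malformed GT at biallelic record ", fix[j, "CHROM"], ":", fix[j, "POS"],
         call. = FALSE)
  }
  dosage[, flagged] <- NA_integer_

  depth <- NULL
  fmt <- vcf@gt[, 1]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    depth <- t(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    storage.mode(depth) <- "integer"
  }

  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos, ref = ref, alt = alt,
                      is_indel = is_indel, is_multiallelic = is_multi,
                      is_nondiploid = is_nondiploid, stringsAsFactors = FALSE)
  genotype_matrix(dosage, sites = sites, depth = depth, samples = samples)
}

# Every data line must have as many tab-separated fields as the #CHROM
# header declares; report the first offending 1-based line number.
validate_vcf_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line", call. = FALSE)
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  counts <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  bad <- body[counts != n_fields]
  if (length(bad)) {
    stop("malformed VCF record at line ", bad[1], ": expected ", n_fields,
         " fields, found ", counts[body == bad[1]][1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal, valid VCF v4.2 with GT (and DP when depth is present)
#' per sample. Heterozygotes are always written `0/1`, missing genotypes
#' `./.`, missing depths `.`.
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  has_dp <- !is.null(x$depth)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=cavepop",
    paste0("##contig=<ID=", unique(x$sites$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  writeLines(meta, con)
  if (n_sites(x) == 0L) return(invisible(path))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$dosage + 1L],
                   nrow = n_samples(x), ncol = n_sites(x))
  gt_str[is.na(gt_str)] <- "./."
  if (has_dp) {
    dp_str <- ifelse(is.na(x$depth), ".", as.character(x$depth))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"),
                     nrow = n_samples(x))
  }
  recs <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                ".", ".", ".", if (has_dp) "GT:DP" else "GT", sep = "\t")
  body <- paste(recs, apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
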