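#' Sample-to-population map
#'
#' @param sample Character vector of sample identifiers (unique).
#' @param population Character vector of population (deme/cave) labels,
#'   same length.
#'
#' @return A data frame of class `popmap` with columns `sample` and
#'   `population`.
#' @export
popmap <- function(sample, population) {
  sample <- as.character(sample)
  population <- as.character(population)
  if (length(sample) != length(population)) {
    stop("`sample` and `population` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample)) {
    stop("duplicate sample in population map: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample = sample, population = population,
                    stringsAsFactors = FALSE)
  class(out) <- c("popmap", "data.frame")
  out
}

#' Read a two-column TSV population map
#'
#' The file has one row per sample: sample identifier, then population
#' label, tab-separated, no header (a header line `sample<TAB>population`
#' is tolerated and skipped).
#'
#' @param path Path to the TSV file.
#' @return A [popmap()] object.
#' @export
read_popmap <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "")
  if (ncol(tab) != 2L) {
    stop("population map must have exactly 2 tab-separated columns, got ",
         ncol(tab), call. = FALSE)
  }
  if (nrow(tab) && identical(tolower(unlist(tab[1, ])), c("sample", "population"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  popmap(tab[[1]], tab[[2]])
}

#' Write a population map as TSV
#'
#' @param pm A [popmap()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  write.table(pm[, c("sample", "population")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Match a popmap against an object's samples; error on unlabelled samples.
# Returns the population label vector aligned to x$samples.
align_popmap <- function(x, pm) {
  idx <- match(x$samples, pm$sample)
  if (anyNA(idx)) {
    stop("samples missing from population map: ",
         paste(x$samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  setNames(pm$population[idx], x$samples)
}

# Row indices of a population's samples, with existence check.
pop_rows <- function(x, pm, population) {
  labels <- align_popmap(x, pm)
  rows <- which(labels == population)
  if (!length(rows)) stop("population not present: ", population, call. = FALSE)
  rows
}
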