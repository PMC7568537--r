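# Bundled reference tables from a four-cave 2bRAD survey of two
# troglobionts on the southern Cumberland Plateau (the spider Nesticus
# barri and the small carrion beetle Ptomaphagus hatchi). These reported
# summary values serve as worked-example inputs for the arithmetic layers
# (Ne from pi, migration-rate inversion, the pi-vs-cave-length
# regression); the underlying read data are not shipped.

#' Cave survey table
#'
#' Cave names, survey numbers, mapped lengths (m), watershed, and the
#' number of individuals sampled per species.
#'
#' @return Data frame with one row per cave.
#' @export
cave_survey <- function() {
  read.table(system.file("extdata", "cave_survey.tsv", package = "cavepop"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Reported pairwise differentiation table
#'
#' Pairwise F_ST estimates between the four caves for each species:
#' genotype-likelihood-based weighted and unweighted F_ST, hard-call
#' Weir-Cockerham F_ST (`weir`), and d_XY.
#'
#' @return Data frame with one row per cave pair and species.
#' @export
published_fst_table <- function() {
  read.table(system.file("extdata", "published_fst.tsv", package = "cavepop"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Reported nucleotide-diversity table
#'
#' Per-cave, per-species nucleotide diversity and the derived effective
#' population sizes (at mu = 2.8e-9), for the genotype-likelihood (`_gl`)
#' and hard-call (`_hard`) tracks, plus cave length.
#'
#' @return Data frame with one row per cave and species.
#' @export
published_diversity_table <- function() {
  read.table(system.file("extdata", "published_diversity.tsv", package = "cavepop"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
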