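# Packaged fixtures: the printed differential-expression tables of the
# study design this package models (top miRNA hits with cytoband and
# nearest-common-fragile-site annotation for the iron-exposure and the
# oncogenic-transformation comparisons; the 28 top protein targets), plus a
# small synthetic reconstruction of the displayed miRNA-target network.

.fixtureRegistry <- function() {
  data.frame(stringsAsFactors = FALSE, check.names = FALSE,
    file = c("table1_fac_vs_unt.tsv", "table2_ocv_vs_cv.tsv",
             "table3_fac_protein_targets.tsv",
             "fig5_target_map_synthetic.tsv"),
    description = c(
      paste("Top 35 miRNA hits, iron-exposed (FAC) vs untreated cells:",
            "signed fold change, FDR p, cytoband, nearest common",
            "fragile site"),
      paste("Top 45 miRNA hits, oncogenic-cocktail (OCV) vs control-virus",
            "cells: signed fold change, FDR p, cytoband, nearest common",
            "fragile site"),
      paste("Top 28 protein targets (> fourfold change), FAC vs untreated:",
            "gene symbol, alias, cytoband, raw LFQ intensity ratio"),
      paste("SYNTHETIC reconstruction of the displayed miRNA-target",
            "network: the per-miRNA target counts (7/3/7), PAX8 as the",
            "common target and the ALDH1A2 edge are faithful; the",
            "remaining gene symbols are plausible stand-ins drawn from",
            "the protein-target table")))
}

#' Path of a packaged fixture file
#'
#' @param name fixture file name (see [listFixtures()]).
#' @return absolute path.
#' @export
fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "mirProt", mustWork = FALSE)
  if (!nzchar(p)) stop("unknown fixture: ", sQuote(name))
  p
}

#' Registry of packaged fixtures
#'
#' @return a data.frame with `file`, `rows` (counted at call time) and
#'   `description`.
#' @export
listFixtures <- function() {
  reg <- .fixtureRegistry()
  reg$rows <- vapply(reg$file, function(f)
    nrow(read.delim(fixturePath(f))), integer(1), USE.NAMES = FALSE)
  reg[, c("file", "rows", "description")]
}

#' Read a packaged miRNA differential-expression table
#'
#' @param file path to a miRNA fixture TSV (`table1_fac_vs_unt.tsv` or
#'   `table2_ocv_vs_cv.tsv`) with columns `mirnaId`, `cytoband`,
#'   `foldChangeSigned`, `fdrP`, `fragileSite`.
#' @return a data.frame with the file's columns plus the back-computed
#'   raw-scale `ratio`.
#' @export
readMirnaFixture <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("mirnaId", "cytoband", "foldChangeSigned", "fdrP",
            "fragileSite")
  stopifnot(all(need %in% colnames(df)))
  df$ratio <- signedFoldToRatio(df$foldChangeSigned)
  df
}

#' Read a packaged protein-target table
#'
#' @param file path to a protein fixture TSV
#'   (`table3_fac_protein_targets.tsv`) with columns `geneName`, `alias`,
#'   `cytoband`, `ratio` (raw-scale LFQ intensity ratio, treatment over
#'   control).
#' @return a data.frame.
#' @export
readProteinFixture <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("geneName", "cytoband", "ratio") %in% colnames(df)))
  df
}

#' Build a locus map from a miRNA fixture table
#'
#' @param df a [readMirnaFixture()] table (or any data.frame with
#'   `mirnaId`, `cytoband`, `fragileSite`).
#' @return a data.frame usable by [annotateLoci()] and
#'   [summarizeByLocus()].
#' @export
locusMapFromFixture <- function(df) {
  stopifnot(all(c("mirnaId", "cytoband", "fragileSite") %in%
                  colnames(df)))
  unique(df[, c("mirnaId", "cytoband", "fragileSite")])
}
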