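# Integration of the two screens: inverse-expression miRNA-to-protein
# pairing over a target map, common-target intersection, and per-locus
# network summaries.

#' Pair differentially expressed miRNAs with inversely regulated proteins
#'
#' Emits a (miRNA, gene) edge iff (1) the edge is in the target map, (2)
#' the miRNA changes at least `mirnaMinFold`-fold in either direction, (3)
#' the protein changes at least `proteinMinFold`-fold in either direction,
#' and (4) the two directions are opposite (miRNA up with protein down, or
#' miRNA down with protein up). Gene symbols are matched case-insensitively
#' and exactly (no alias resolution). Output rows are ordered
#' lexicographically by (miRNA, gene) and are always a subset of the map's
#' edges. Statistical significance is expected to be enforced upstream
#' (through [mirnaDETest()] / [classifyTargets()] tier selection of the
#' record tables passed in).
#'
#' @param mirnaRecords data.frame-like with `mirnaId` and
#'   `foldChangeSigned` (e.g. [mirnaDETest()] output or a printed-table
#'   fixture).
#' @param proteinRecords data.frame-like with `geneName` and `ratio` (e.g.
#'   [proteinDE()] output or a printed-table fixture).
#' @param map a [TargetMap-class].
#' @param mirnaMinFold,proteinMinFold fold cutoffs (defaults 4 and 4, the
#'   "top hits" setting; use 2 for the permissive miRNA tier).
#' @return a [S4Vectors::DataFrame] of paired hits: `mirnaId`,
#'   `mirnaSignedFold`, `geneSymbol`, `proteinRatio`, `direction`
#'   (`mirna_down_protein_up` / `mirna_up_protein_down`), `evidence`.
#' @export
pairInverse <- function(mirnaRecords, proteinRecords, map,
                        mirnaMinFold = 4, proteinMinFold = 4) {
  stopifnot(all(c("mirnaId", "foldChangeSigned") %in%
                  colnames(mirnaRecords)),
            all(c("geneName", "ratio") %in% colnames(proteinRecords)),
            is(map, "TargetMap"), mirnaMinFold >= 1, proteinMinFold >= 1)
  edges <- as.data.frame(targetEdges(map))
  if (!nrow(edges)) {
    return(DataFrame(mirnaId = character(), mirnaSignedFold = numeric(),
                     geneSymbol = character(), proteinRatio = numeric(),
                     direction = character(), evidence = character()))
  }
  mi <- match(edges$mirnaId, mirnaRecords$mirnaId)
  pi <- match(tolower(edges$geneSymbol),
              tolower(proteinRecords$geneName))
  sf <- mirnaRecords$foldChangeSigned[mi]
  pr <- proteinRecords$ratio[pi]
  mPass <- !is.na(sf) & abs(sf) >= mirnaMinFold
  pPass <- !is.na(pr) & (pr >= proteinMinFold | pr <= 1 / proteinMinFold)
  opposite <- !is.na(sf) & !is.na(pr) &
    (sign(sf) != sign(log(pr))) & log(pr) != 0
  keep <- which(mPass & pPass & opposite)
  out <- DataFrame(
    mirnaId = edges$mirnaId[keep],
    mirnaSignedFold = sf[keep],
    geneSymbol = edges$geneSymbol[keep],
    proteinRatio = pr[keep],
    direction = ifelse(sf[keep] < 0, "mirna_down_protein_up",
                       "mirna_up_protein_down"),
    evidence = edges$evidence[keep])
  out[order(out$mirnaId, out$geneSymbol), , drop = FALSE]
}

#' Genes targeted by every miRNA in a subset
#'
#' Intersection over the per-miRNA target-gene sets of a target map or a
#' paired-hit table.
#'
#' @param x a [TargetMap-class] or a [pairInverse()] result.
#' @param mirnaSubset character vector of miRNA identifiers.
#' @return sorted character vector of common gene symbols (upper-cased for
#'   the case-insensitive intersection).
#' @export
commonTargets <- function(x, mirnaSubset) {
  edges <- if (is(x, "TargetMap")) as.data.frame(targetEdges(x)) else
    data.frame(mirnaId = x$mirnaId, geneSymbol = x$geneSymbol,
               stringsAsFactors = FALSE)
  stopifnot(length(mirnaSubset) >= 1L)
  sets <- lapply(mirnaSubset, function(m)
    unique(toupper(edges$geneSymbol[edges$mirnaId == m])))
  sort(Reduce(intersect, sets))
}

#' Per-cytoband counts of distinct paired miRNAs and targets
#'
#' @param pairedHits a [pairInverse()] result.
#' @param locusMap data.frame with `mirnaId`, `cytoband`, `fragileSite`
#'   columns; hits whose miRNA is absent count under `"unknown"`.
#' @return a data.frame with `cytoband`, `nMirnas`, `nTargets`; distinct
#'   miRNA counts sum to the total number of distinct paired miRNAs.
#' @export
summarizeByLocus <- function(pairedHits, locusMap) {
  if (!nrow(pairedHits))
    return(data.frame(cytoband = character(), nMirnas = integer(),
                      nTargets = integer(), stringsAsFactors = FALSE))
  cb <- locusMap$cytoband[match(pairedHits$mirnaId, locusMap$mirnaId)]
  cb[is.na(cb)] <- "unknown"
  df <- data.frame(cytoband = cb, mirnaId = pairedHits$mirnaId,
                   gene = toupper(pairedHits$geneSymbol),
                   stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$cytoband), function(s)
    data.frame(cytoband = s$cytoband[1],
               nMirnas = length(unique(s$mirnaId)),
               nTargets = length(unique(s$gene)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$cytoband), , drop = FALSE]
}
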