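# miRNA array differential expression: probe de-duplication, per-feature
# two-sample tests with BH-FDR, the signed fold-change convention, tier
# selection, cytoband / common-fragile-site annotation and locus summaries.

#' Collapse duplicated probe identifiers by per-sample median
#'
#' Array exports occasionally repeat a feature identifier (e.g. duplicated
#' snoRNA probes); duplicates are collapsed to a single row holding the
#' per-sample median. The number of collapsed identifiers is recorded in
#' `metadata()$dedupeLog`.
#'
#' @param x an [IntensityExperiment-class].
#' @return an `IntensityExperiment` with unique row names, first-occurrence
#'   order preserved.
#' @export
dedupeProbes <- function(x) {
  ids <- rownames(x)
  if (!anyDuplicated(ids)) {
    metadata(x)$dedupeLog <- list(nCollapsed = 0L)
    return(x)
  }
  m <- intensities(x)
  keep <- unique(ids)
  out <- matrix(NA_real_, length(keep), ncol(m),
                dimnames = list(keep, colnames(m)))
  for (id in keep) {
    rows <- m[ids == id, , drop = FALSE]
    out[id, ] <- if (nrow(rows) == 1L) rows[1L, ] else
      apply(rows, 2L, median, na.rm = TRUE)
  }
  res <- IntensityExperiment(out, as.character(sampleGroups(x)))
  metadata(res)$dedupeLog <-
    list(nCollapsed = sum(table(ids) > 1L))
  res
}

#' Signed fold-change convention
#'
#' Maps a raw-scale ratio to the signed convention used in array reporting:
#' ratios of at least 1 are reported as `+ratio`, ratios below 1 as
#' `-1/ratio` (e.g. 1/111.69 becomes -111.69). A strictly monotone
#' bijection from (0, Inf) onto (-Inf, -1] U [1, Inf);
#' [signedFoldToRatio()] is its inverse.
#'
#' @param ratio raw-scale fold change(s), > 0.
#' @return signed fold change(s).
#' @export
signedFold <- function(ratio) {
  stopifnot(all(ratio > 0))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' @rdname signedFold
#' @param sf signed fold change(s), |sf| >= 1.
#' @export
signedFoldToRatio <- function(sf) {
  stopifnot(all(abs(sf) >= 1))
  ifelse(sf >= 1, sf, -1 / sf)
}

#' miRNA differential-expression test
#'
#' Per-feature two-sided two-sample t-test of the second group versus the
#' first on log2 intensities (equal-variance by default, the array
#' convention at n = 3; Welch optional), with raw p, BH-adjusted FDR, the
#' raw-scale ratio (geometric, `2^` mean log2 difference), the signed fold
#' change, and tier selection: `twofold` iff at least 2-fold in either
#' direction with selection p < `pMax`; `fourfold` analogously at 4-fold.
#' Selection uses the raw p-value by default (`useFdr = TRUE` switches to
#' the BH-adjusted value).
#'
#' @param x an [IntensityExperiment-class], raw scale, no missing values.
#' @param varEqual use the pooled-variance t-test (default TRUE).
#' @param pMax selection threshold (default 0.05).
#' @param useFdr select on BH-FDR instead of raw p.
#' @return a [S4Vectors::DataFrame] with `mirnaId`, `ratio`,
#'   `foldChangeSigned`, `pRaw`, `fdrBH`, `tier`
#'   (`none` < `twofold` < `fourfold`).
#' @export
mirnaDETest <- function(x, varEqual = TRUE, pMax = 0.05, useFdr = FALSE) {
  m <- intensities(x)
  if (anyNA(m)) stop("miRNA matrix contains missing values")
  g <- sampleGroups(x)
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  ctrl <- which(g == levels(g)[1])
  treat <- which(g == levels(g)[2])
  lm2 <- log2(m)
  p <- apply(lm2, 1L, function(r) {
    a <- r[treat]
    b <- r[ctrl]
    if (sd(a) == 0 && sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    t.test(a, b, var.equal = varEqual)$p.value
  })
  log2fc <- rowMeans(lm2[, treat, drop = FALSE]) -
    rowMeans(lm2[, ctrl, drop = FALSE])
  ratio <- 2^log2fc
  fdr <- p.adjust(p, method = "BH")
  psel <- if (useFdr) fdr else p
  two <- (ratio >= 2 | ratio <= 0.5) & psel < pMax
  four <- (ratio >= 4 | ratio <= 0.25) & psel < pMax
  tiers <- c("none", "twofold", "fourfold")
  res <- DataFrame(mirnaId = rownames(m), ratio = ratio,
                   foldChangeSigned = signedFold(ratio), pRaw = p,
                   fdrBH = fdr,
                   tier = factor(tiers[1L + two + four], levels = tiers),
                   row.names = rownames(m))
  metadata(res) <- list(control = levels(g)[1], treatment = levels(g)[2],
                        varEqual = varEqual, pMax = pMax, useFdr = useFdr)
  res
}

#' Attach cytoband and nearest-common-fragile-site annotation
#'
#' @param records data.frame-like with a `mirnaId` column.
#' @param locusMap data.frame with columns `mirnaId`, `cytoband`,
#'   `fragileSite` (see [locusMapFromFixture()]); lookups are total —
#'   unknown identifiers annotate to NA, never an error.
#' @return `records` with `cytoband` and `nearestFragileSite` columns.
#' @export
annotateLoci <- function(records, locusMap) {
  stopifnot("mirnaId" %in% colnames(records),
            all(c("mirnaId", "cytoband", "fragileSite") %in%
                  colnames(locusMap)))
  idx <- match(records$mirnaId, locusMap$mirnaId)
  records$cytoband <- locusMap$cytoband[idx]
  records$nearestFragileSite <- locusMap$fragileSite[idx]
  records
}

#' Fraction of records at a cytoband prefix
#'
#' Prefix match on the cytoband (e.g. `"14q32"` aggregates 14q32.2 and
#' 14q32.31, the way locus-level summaries are reported).
#'
#' @param records data.frame-like with a `cytoband` column.
#' @param prefix cytoband prefix.
#' @return a list with `count`, `total` and `percent`
#'   (100 * count / total, rounded to 2 decimals; NA when `total` is 0).
#' @export
locusFraction <- function(records, prefix) {
  cb <- as.character(records$cytoband)
  total <- length(cb)
  count <- sum(startsWith(cb[!is.na(cb)], prefix))
  list(count = count, total = total,
       percent = if (total > 0) round(100 * count / total, 2) else
         NA_real_)
}

#' Exact partition of two identifier sets
#'
#' @param a,b character vectors (duplicates ignored).
#' @return a list with `onlyA`, `shared`, `onlyB` (sorted).
#' @export
overlapSets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  list(onlyA = sort(setdiff(a, b)), shared = sort(intersect(a, b)),
       onlyB = sort(setdiff(b, a)))
}
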