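# Relative qPCR quantification by the comparative CT (2^-ddCT) method with
# reference-gene normalization, amplification efficiency fixed at 2.

#' Relative quantification by 2^-ddCT
#'
#' Livak comparative-CT quantification: per sample,
#' `dCT = CT(target) - CT(reference)`; then
#' `ddCT = mean dCT(treated) - mean dCT(calibrator)` and the fold change of
#' the treated group relative to the calibrator is `2^-ddCT`
#' (amplification efficiency fixed at exactly 2, the assumption of the
#' method; group aggregation by arithmetic mean of dCT). Adding a constant
#' to every CT of a sample cancels in dCT, so the result is invariant to
#' per-sample CT offsets.
#'
#' @param ct a CT table data.frame with columns `sampleId`, `group`,
#'   `target`, `ct` (see [readCTTable()] / [simulateCTTable()]).
#' @param target target assay name.
#' @param treatedGroup,calibratorGroup group labels.
#' @param reference reference assay name (default `"RNU6B"`).
#' @return a list with `foldChange`, `ddCt`, and `deltaCt` (per-sample
#'   data.frame with `sampleId`, `group`, `deltaCt`).
#' @examples
#' ct <- simulateCTTable(trueFoldChanges = c(1, 1 / 16), noiseSd = 0)
#' ddctFoldChange(ct, "miR-432-5p", "FAC", "UNT")$foldChange # 0.0625
#' @export
ddctFoldChange <- function(ct, target, treatedGroup, calibratorGroup,
                           reference = "RNU6B") {
  need <- c("sampleId", "group", "target", "ct")
  stopifnot(all(need %in% colnames(ct)))
  sub <- ct[ct$group %in% c(treatedGroup, calibratorGroup), , drop = FALSE]
  if (anyDuplicated(paste(sub$sampleId, sub$target)))
    stop("duplicated (sample, target) CT entries")
  tgt <- sub[sub$target == target, , drop = FALSE]
  ref <- sub[sub$target == reference, , drop = FALSE]
  if (!nrow(tgt)) stop("no CT values for target ", sQuote(target))
  noRef <- setdiff(tgt$sampleId, ref$sampleId)
  if (length(noRef))
    stop("missing reference (", reference, ") CT for sample(s): ",
         paste(noRef, collapse = ", "))
  dct <- tgt$ct - ref$ct[match(tgt$sampleId, ref$sampleId)]
  deltaCt <- data.frame(sampleId = tgt$sampleId, group = tgt$group,
                        deltaCt = dct, stringsAsFactors = FALSE)
  for (g in c(treatedGroup, calibratorGroup))
    if (!any(deltaCt$group == g))
      stop("no usable samples in group ", sQuote(g))
  ddct <- mean(deltaCt$deltaCt[deltaCt$group == treatedGroup]) -
    mean(deltaCt$deltaCt[deltaCt$group == calibratorGroup])
  list(foldChange = 2^-ddct, ddCt = ddct, deltaCt = deltaCt)
}

#' Express a fold change as a signed percent change
#'
#' Folds below 1 are reported as a percent *reduction*,
#' `(1 - fold) * 100`; folds of at least 1 as a percent *increase*,
#' `(fold - 1) * 100` — the reporting convention of qPCR validation
#' results (a fold of 0.001 is a 99.9% reduction).
#'
#' @param fold raw-scale fold change(s), > 0.
#' @return a data.frame with columns `fold`, `percent`, `direction`
#'   (`"reduction"` or `"increase"`).
#' @export
percentChange <- function(fold) {
  stopifnot(all(fold > 0))
  data.frame(
    fold = fold,
    percent = ifelse(fold < 1, (1 - fold) * 100, (fold - 1) * 100),
    direction = ifelse(fold < 1, "reduction", "increase"),
    stringsAsFactors = FALSE)
}
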