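# LFQ proteomics differential-expression stage: protein-groups cleaning,
# valid-value filtering, downshifted-Gaussian MNAR imputation, Welch test,
# z-score standardization, ratio tiering, CV summaries.

.flagSet <- function(v) {
  if (is.null(v)) return(logical(0))
  v <- trimws(as.character(v))
  !is.na(v) & v %in% c("+", "TRUE", "true", "1", "yes")
}

#' Remove decoy/contaminant/site-only rows and zero intensities
#'
#' Drops every row with the `Reverse`, `Potential contaminant` or
#' `Only identified by site` flag set, and converts zero LFQ intensities to
#' missing. The per-reason drop counts are attached as
#' `attr(, "filterLog")`.
#'
#' @param df a protein-groups data.frame from [readProteinGroups()].
#' @return the cleaned data.frame, with a `filterLog` attribute
#'   (`nInput`, `nReverse`, `nContaminant`, `nSiteOnly`, `nRetained`).
#' @export
cleanProteinGroups <- function(df) {
  stopifnot(all(.pgCols %in% colnames(df)))
  rev <- .flagSet(df$Reverse)
  con <- .flagSet(df[["Potential contaminant"]])
  site <- .flagSet(df[["Only identified by site"]])
  keep <- !(rev | con | site)
  out <- df[keep, , drop = FALSE]
  lfq <- grep("^LFQ intensity ", colnames(out), value = TRUE)
  for (cc in lfq) {
    v <- as.numeric(out[[cc]])
    v[!is.na(v) & v == 0] <- NA_real_
    out[[cc]] <- v
  }
  rownames(out) <- NULL
  attr(out, "filterLog") <- list(
    nInput = nrow(df), nReverse = sum(rev), nContaminant = sum(con),
    nSiteOnly = sum(site), nRetained = nrow(out))
  out
}

#' Assemble an [IntensityExperiment-class] from a cleaned protein table
#'
#' @param df output of [cleanProteinGroups()].
#' @param groups named list of two character vectors of sample names (as in
#'   the `LFQ intensity <sample>` column suffixes), control group first,
#'   e.g. `list(UNT = c("UNT_1", ...), FAC = c("FAC_1", ...))`.
#' @return an `IntensityExperiment` with `proteinId`/`geneName` in
#'   `rowData`.
#' @export
asIntensityExperiment <- function(df, groups) {
  stopifnot(is.list(groups), length(groups) == 2L,
            !is.null(names(groups)))
  cols <- paste("LFQ intensity", unlist(groups))
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stop("sample column(s) not found: ", paste(sQuote(missing),
                                               collapse = ", "))
  m <- as.matrix(df[, cols, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[["Protein IDs"]]
  colnames(m) <- unlist(groups)
  IntensityExperiment(
    m, rep(names(groups), lengths(groups)),
    rowData = DataFrame(proteinId = df[["Protein IDs"]],
                        geneName = df[["Gene names"]]))
}

#' Valid-value filter
#'
#' Retains a feature iff it has at least `minValid` observed (non-missing)
#' values in at least one group (`rule = "any"`, the convention that keeps
#' group-absent proteins so MNAR imputation can fill the absent group), or
#' in each group (`rule = "both"`, the strict mode).
#'
#' @param x an [IntensityExperiment-class].
#' @param minValid minimum observed values per group (default 3, i.e. at
#'   most 2 missing out of 5 replicates).
#' @param rule `"any"` (default) or `"both"`.
#' @return the filtered `IntensityExperiment`, with the number of rows
#'   removed in `metadata(x)$validValueLog`.
#' @export
filterValidValues <- function(x, minValid = 3, rule = c("any", "both")) {
  rule <- match.arg(rule)
  m <- intensities(x)
  g <- sampleGroups(x)
  sizes <- table(g)
  if (minValid > min(sizes))
    stop("minValid (", minValid, ") exceeds the smallest group size (",
         min(sizes), ")")
  obs <- vapply(levels(g), function(l)
    rowSums(!is.na(m[, g == l, drop = FALSE])), numeric(nrow(m)))
  keep <- if (rule == "any") {
    apply(obs >= minValid, 1L, any)
  } else {
    apply(obs >= minValid, 1L, all)
  }
  out <- x[keep, ]
  metadata(out)$validValueLog <- list(nInput = nrow(m),
                                      nRetained = sum(keep),
                                      minValid = minValid, rule = rule)
  out
}

#' Downshifted-Gaussian imputation of left-censored missing values
#'
#' Per sample column, the mean `m` and sd `s` of the observed log2 values
#' are computed and every missing entry is drawn independently from
#' `Normal(m - downshift * s, (width * s)^2)` — the standard model for
#' intensities that are missing because they fell below the detection
#' limit. Observed entries are returned bit-identical.
#'
#' @param mat numeric matrix on the log2 scale, NA marking missing values.
#' @param width imputation width as a fraction of the per-column observed
#'   sd (default 0.3).
#' @param downshift downshift in multiples of the per-column observed sd
#'   (default 1.8; use 1.75 for the transformed-versus-control comparison).
#' @param seed RNG seed.
#' @return the matrix with missing entries filled in.
#' @export
imputeMNAR <- function(mat, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(is.matrix(mat), width > 0, downshift >= 0)
  nObs <- colSums(!is.na(mat))
  if (any(nObs < 2L))
    stop("column(s) with fewer than 2 observed values (sd undefined): ",
         paste(colnames(mat)[nObs < 2L], collapse = ", "))
  if (!anyNA(mat)) return(mat)
  set.seed(as.integer(seed))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    m <- mean(mat[!miss, j])
    s <- sd(mat[!miss, j])
    out[miss, j] <- rnorm(sum(miss), m - downshift * s, width * s)
  }
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs where both groups have zero
#' variance return `p = 1` when the means are equal (no evidence of a
#' difference) and `p = 0` otherwise, by documented convention.
#'
#' @param a,b numeric vectors (at least 2 values each).
#' @return a list with elements `t`, `df`, `p`.
#' @export
welchTest <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Standardize log2 fold changes to z-scores
#'
#' `z = (x - mean(x)) / sd(x)` with the sample sd (denominator n - 1) —
#' the standardization of the per-protein mean log2 ratio across all
#' quantified proteins that the combined p/z filter operates on.
#'
#' @param log2fc numeric vector of per-feature log2 fold changes (at least
#'   2 finite values, non-zero spread).
#' @return the z-score vector (mean 0, sd 1).
#' @export
computeZScores <- function(log2fc) {
  x <- log2fc[is.finite(log2fc)]
  if (length(x) < 2L) stop("need at least 2 finite values")
  s <- sd(x)
  if (s == 0) stop("zero spread: z-scores undefined")
  (log2fc - mean(x)) / s
}

#' Combined significance/fold-change tier classification
#'
#' Tiers a differential-expression table by the combined filter:
#' `significant` iff `p < pMax` and `|z| > zMin`; `differential` iff
#' additionally the raw-scale ratio is at least `ratioMin`-fold in either
#' direction (default 2); `top` iff at least `topRatioMin`-fold (default
#' 4). The chain `top` within `differential` within `significant` holds by
#' construction.
#'
#' @param records data.frame-like with columns `pRaw`, `z`, `ratio`.
#' @param pMax,zMin,ratioMin,topRatioMin filter thresholds.
#' @return `records` with logical columns `significant`, `differential`,
#'   `top` and a `tier` factor (`not_significant` < `significant` <
#'   `differential` < `top`).
#' @export
classifyTargets <- function(records, pMax = 0.05, zMin = 1, ratioMin = 2,
                            topRatioMin = 4) {
  stopifnot(all(c("pRaw", "z", "ratio") %in% colnames(records)))
  sig <- records$pRaw < pMax & abs(records$z) > zMin
  dif <- sig & (records$ratio >= ratioMin | records$ratio <= 1 / ratioMin)
  top <- sig & (records$ratio >= topRatioMin |
                  records$ratio <= 1 / topRatioMin)
  records$significant <- sig
  records$differential <- dif
  records$top <- top
  tiers <- c("not_significant", "significant", "differential", "top")
  records$tier <- factor(tiers[1L + sig + dif + top], levels = tiers)
  records
}

#' Per-group coefficient-of-variation summary
#'
#' For every feature and group, CV = sd / mean over the observed raw-scale
#' intensities (features with fewer than 2 observed values in a group are
#' skipped for that group); the average and median CV across features are
#' reported per group, in percent.
#'
#' @param x an [IntensityExperiment-class] on the raw scale.
#' @return a data.frame with columns `group`, `meanCV`, `medianCV`
#'   (percent).
#' @export
cvSummary <- function(x) {
  m <- intensities(x)
  g <- sampleGroups(x)
  res <- lapply(levels(g), function(l) {
    sub <- m[, g == l, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, sd, na.rm = TRUE)
    n <- rowSums(!is.na(sub))
    cv <- ifelse(n >= 2L, s / mu, NA_real_)
    data.frame(group = l, meanCV = 100 * mean(cv, na.rm = TRUE),
               medianCV = 100 * median(cv, na.rm = TRUE))
  })
  do.call(rbind, res)
}

#' LFQ differential-expression pipeline
#'
#' Runs the post-search stage end to end on a raw-scale intensity object:
#' valid-value filtering, log2 transform, downshifted-Gaussian MNAR
#' imputation, per-protein Welch test of treatment versus control, z-score
#' standardization of the log2 fold changes, and combined-filter tiering.
#'
#' The reported `ratio` (treatment over control) uses the geometric
#' convention `2^log2fc` by default; `ratioMethod = "arithmetic"` instead
#' reports the ratio of arithmetic group means of the (imputed) raw-scale
#' intensities.
#'
#' @param x an [IntensityExperiment-class], raw scale; the first group
#'   level is the control.
#' @param width,downshift,seed imputation parameters (see [imputeMNAR()]).
#' @param minValid,rule valid-value filter (see [filterValidValues()]).
#' @param ratioMethod `"geometric"` (default) or `"arithmetic"`.
#' @param pMax,zMin tier thresholds (see [classifyTargets()]).
#' @return a [S4Vectors::DataFrame] with one row per retained protein:
#'   `proteinId`, `geneName`, `meanLog2Ctrl`, `meanLog2Treat`, `log2fc`,
#'   `ratio`, `welchT`, `welchDf`, `pRaw`, `z`, `nImputedCtrl`,
#'   `nImputedTreat`, tier columns; run parameters in `metadata()`.
#' @examples
#' sim <- simulateLFQ(simConfig(nFeatures = 300, seed = 2))
#' de <- proteinDE(sim, seed = 2)
#' table(de$tier)
#' @export
proteinDE <- function(x, width = 0.3, downshift = 1.8, seed = 1L,
                      minValid = 3, rule = c("any", "both"),
                      ratioMethod = c("geometric", "arithmetic"),
                      pMax = 0.05, zMin = 1) {
  rule <- match.arg(rule)
  ratioMethod <- match.arg(ratioMethod)
  x <- filterValidValues(x, minValid = minValid, rule = rule)
  g <- sampleGroups(x)
  ctrl <- levels(g)[1]
  treat <- levels(g)[2]
  raw <- intensities(x)
  log2m <- log2(raw)
  nImpC <- rowSums(is.na(log2m[, g == ctrl, drop = FALSE]))
  nImpT <- rowSums(is.na(log2m[, g == treat, drop = FALSE]))
  imp <- imputeMNAR(log2m, width = width, downshift = downshift,
                    seed = seed)
  cIdx <- which(g == ctrl)
  tIdx <- which(g == treat)
  mC <- rowMeans(imp[, cIdx, drop = FALSE])
  mT <- rowMeans(imp[, tIdx, drop = FALSE])
  log2fc <- mT - mC
  ratio <- if (ratioMethod == "geometric") {
    2^log2fc
  } else {
    rowMeans(2^imp[, tIdx, drop = FALSE]) /
      rowMeans(2^imp[, cIdx, drop = FALSE])
  }
  wt <- apply(imp, 1L, function(r) {
    res <- welchTest(r[tIdx], r[cIdx])
    c(res$t, res$df, res$p)
  })
  rd <- rowData(x)
  res <- DataFrame(
    proteinId = if ("proteinId" %in% colnames(rd)) rd$proteinId else
      rownames(raw),
    geneName = if ("geneName" %in% colnames(rd)) rd$geneName else
      rownames(raw),
    meanLog2Ctrl = mC, meanLog2Treat = mT, log2fc = log2fc, ratio = ratio,
    welchT = wt[1L, ], welchDf = wt[2L, ], pRaw = wt[3L, ],
    z = computeZScores(log2fc),
    nImputedCtrl = nImpC, nImputedTreat = nImpT,
    row.names = rownames(raw))
  res <- classifyTargets(res, pMax = pMax, zMin = zMin)
  metadata(res) <- list(control = ctrl, treatment = treat, width = width,
                        downshift = downshift, seed = as.integer(seed),
                        minValid = minValid, rule = rule,
                        ratioMethod = ratioMethod,
                        validValueLog = metadata(x)$validValueLog)
  res
}
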