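#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData rowData<-
#' @importFrom stats median p.adjust pnorm plogis pt qt quantile rnorm runif
#'   sd t.test uniroot setNames dnorm integrate
#' @importFrom utils read.delim write.table
NULL

#' Simulation configuration for two-group intensity screens
#'
#' Holds every knob of the synthetic-data generators: problem size, group
#' labels, the log2-intensity background, the within-group coefficient of
#' variation, the planted differential-expression structure, and the
#' intensity-dependent (MNAR) missingness model.
#'
#' Within-group spread is derived from `cv` by the exact log-normal relation
#' `sdlog2 = sqrt(log(1 + cv^2)) / log(2)`, so the realized raw-scale CV of
#' complete features equals `cv` up to Monte-Carlo error.
#'
#' Missingness is logistic in the true log2 intensity: an entry at log2
#' intensity `x` is censored with probability
#' `plogis(-(x - anchor) * mnarSteepness)` where `anchor` is the
#' `mnarCensorQuantile` quantile of the simulated log2 intensities. Setting
#' `mnarCensorQuantile = 0` (or `mnarSteepness = 0`) disables missingness
#' entirely.
#'
#' @slot nFeatures number of simulated features.
#' @slot nPerGroup replicates per group (5 for the proteomics design, 3 for
#'   the miRNA arrays).
#' @slot groupNames two labels; the first is the control/calibrator group.
#' @slot baseLog2Mean,baseLog2Sd between-feature log2-intensity background.
#' @slot cv within-group coefficient of variation (fraction).
#' @slot deFraction fraction of features truly changed.
#' @slot log2fcRange magnitude range (log2 units) of planted effects; signs
#'   are random.
#' @slot mnarCensorQuantile,mnarSteepness missingness model (see above).
#' @slot seed master RNG seed; identical config implies bit-identical output.
#' @seealso [simConfig()], [simulateLFQ()], [simulateMirna()]
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
  nFeatures = "integer",
  nPerGroup = "integer",
  groupNames = "character",
  baseLog2Mean = "numeric",
  baseLog2Sd = "numeric",
  cv = "numeric",
  deFraction = "numeric",
  log2fcRange = "numeric",
  mnarCensorQuantile = "numeric",
  mnarSteepness = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be >= 1")
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (length(object@groupNames) != 2L || anyDuplicated(object@groupNames))
    msg <- c(msg, "groupNames must be two distinct labels")
  if (!(object@cv > 0)) msg <- c(msg, "cv must be > 0")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must be in [0, 1]")
  if (length(object@log2fcRange) != 2L || any(object@log2fcRange < 0) ||
      diff(object@log2fcRange) < 0)
    msg <- c(msg, "log2fcRange must be an increasing non-negative pair")
  if (object@mnarCensorQuantile < 0 || object@mnarCensorQuantile > 1)
    msg <- c(msg, "mnarCensorQuantile must be in [0, 1]")
  if (object@mnarSteepness < 0) msg <- c(msg, "mnarSteepness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' Defaults describe the proteomics arm of the study design the package
#' models: two groups, 5 replicates, ~22% within-group CV, 10% of features
#' truly changed with 2- to 100-fold effects, and low-intensity-biased
#' missingness anchored at the 10th percentile. For the miRNA-array arm use
#' `nPerGroup = 3` and `mnarCensorQuantile = 0` (arrays have no censored
#' entries).
#'
#' @param nFeatures,nPerGroup,groupNames,baseLog2Mean,baseLog2Sd,cv,deFraction
#'   see [SimConfig-class].
#' @param log2fcRange,mnarCensorQuantile,mnarSteepness,seed
#'   see [SimConfig-class].
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(nFeatures = 100, seed = 7)
#' sim <- simulateLFQ(cfg)
#' @export
simConfig <- function(nFeatures = 2000, nPerGroup = 5,
                      groupNames = c("UNT", "FAC"),
                      baseLog2Mean = 25, baseLog2Sd = 2, cv = 0.22,
                      deFraction = 0.1, log2fcRange = c(1, log2(100)),
                      mnarCensorQuantile = 0.1, mnarSteepness = 2,
                      seed = 1L) {
  new("SimConfig",
      nFeatures = as.integer(nFeatures), nPerGroup = as.integer(nPerGroup),
      groupNames = as.character(groupNames),
      baseLog2Mean = as.numeric(baseLog2Mean),
      baseLog2Sd = as.numeric(baseLog2Sd), cv = as.numeric(cv),
      deFraction = as.numeric(deFraction),
      log2fcRange = as.numeric(log2fcRange),
      mnarCensorQuantile = as.numeric(mnarCensorQuantile),
      mnarSteepness = as.numeric(mnarSteepness), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFeatures, "features x 2 groups (",
      paste(object@groupNames, collapse = " vs "), "), n =",
      object@nPerGroup, "per group\n")
  cat("  cv =", object@cv, "| deFraction =", object@deFraction,
      "| |log2fc| in [", object@log2fcRange[1], ",",
      round(object@log2fcRange[2], 3), "]\n")
  cat("  MNAR: censor quantile =", object@mnarCensorQuantile,
      "steepness =", object@mnarSteepness, "| seed =", object@seed, "\n")
})

#' Two-group features-by-samples intensity container
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' holding one raw-scale assay named `"intensity"` (NA marks missing) and a
#' two-level `group` factor in `colData`. Serves both the proteomics LFQ
#' matrix and the miRNA array matrix. Simulators attach their ground truth
#' (`isChanged`, `trueLog2FC`) as `rowData`, retrievable with [simTruth()].
#'
#' @exportClass IntensityExperiment
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
  msg <- character()
  if (!identical(assayNames(object)[1], "intensity"))
    msg <- c(msg, "first assay must be named 'intensity'")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'group'")
  else {
    g <- colData(object)$group
    if (!is.factor(g) || nlevels(g) != 2L)
      msg <- c(msg, "'group' must be a factor with exactly two levels")
  }
  if (length(assays(object)) >= 1L) {
    a <- assay(object, 1L)
    if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an [IntensityExperiment-class]
#'
#' @param intensity numeric matrix (features x samples), raw scale, NA for
#'   missing; zeros are converted to NA (the convention of LFQ exports).
#' @param group sample group labels (coerced to a two-level factor; level
#'   order is the order of first appearance, the first level acting as the
#'   control/calibrator group).
#' @param rowData optional `DataFrame`/data.frame of per-feature columns.
#' @return an `IntensityExperiment`.
#' @export
IntensityExperiment <- function(intensity, group, rowData = NULL) {
  m <- as.matrix(intensity)
  m[!is.na(m) & m == 0] <- NA_real_
  g <- factor(as.character(group), levels = unique(as.character(group)))
  se <- SummarizedExperiment(
    assays = list(intensity = m),
    colData = DataFrame(group = g, row.names = colnames(m)))
  if (!is.null(rowData)) rowData(se) <- DataFrame(rowData)
  new("IntensityExperiment", se)
}

#' @describeIn IntensityExperiment raw-scale intensity matrix (NA = missing).
#' @param x an `IntensityExperiment`.
#' @export
intensities <- function(x) assay(x, "intensity")

#' @describeIn IntensityExperiment per-sample group factor.
#' @export
sampleGroups <- function(x) colData(x)$group

#' @describeIn IntensityExperiment the two group labels
#'   (control/calibrator first).
#' @export
groupLabels <- function(x) levels(sampleGroups(x))

#' @describeIn IntensityExperiment simulation ground truth (`DataFrame` with
#'   `isChanged`, `trueLog2FC`), or NULL when the object does not come from a
#'   simulator.
#' @export
simTruth <- function(x) {
  rd <- rowData(x)
  if (!all(c("isChanged", "trueLog2FC") %in% colnames(rd))) return(NULL)
  rd[, intersect(c("featureId", "geneName", "isChanged", "trueLog2FC"),
                 colnames(rd)), drop = FALSE]
}

setMethod("show", "IntensityExperiment", function(object) {
  a <- assay(object, "intensity")
  cat("IntensityExperiment:", nrow(a), "features x", ncol(a), "samples\n")
  tg <- table(sampleGroups(object))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tg), tg),
                         collapse = ", "), "\n")
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(a))))
  tr <- simTruth(object)
  if (!is.null(tr))
    cat("  simulated truth:", sum(tr$isChanged), "changed features\n")
})

#' miRNA-to-gene target map
#'
#' Open stand-in for a commercial miRNA-target knowledge base: a set of
#' `(mirnaId, geneSymbol, evidence)` edges, with evidence drawn from the
#' closed vocabulary `experimental`, `high`, `moderate` (experimentally
#' determined versus high/moderate-confidence predicted). Edges are unique
#' per (miRNA, gene) pair.
#'
#' @slot edges a `DataFrame` with columns `mirnaId`, `geneSymbol`,
#'   `evidence`.
#' @seealso [TargetMap()], [readTargetMap()], [pairInverse()]
#' @exportClass TargetMap
setClass("TargetMap", slots = c(edges = "DataFrame"))

.evidenceLevels <- c("experimental", "high", "moderate")

setValidity("TargetMap", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("mirnaId", "geneSymbol", "evidence")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (anyDuplicated(paste(e$mirnaId, tolower(e$geneSymbol))))
      msg <- c(msg, "duplicate (mirnaId, geneSymbol) edges")
    if (!all(e$evidence %in% .evidenceLevels))
      msg <- c(msg, paste("evidence must be one of",
                          paste(.evidenceLevels, collapse = "/")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [TargetMap-class]
#'
#' @param edges data.frame-like with columns `mirnaId`, `geneSymbol`,
#'   `evidence` (one of `"experimental"`, `"high"`, `"moderate"`).
#' @return a validated `TargetMap`.
#' @export
TargetMap <- function(edges = data.frame(mirnaId = character(),
                                         geneSymbol = character(),
                                         evidence = character())) {
  new("TargetMap", edges = DataFrame(edges))
}

#' @describeIn TargetMap the edge table as a `DataFrame`.
#' @param x a `TargetMap`.
#' @export
targetEdges <- function(x) x@edges

setMethod("show", "TargetMap", function(object) {
  e <- object@edges
  cat("TargetMap:", nrow(e), "edges,", length(unique(e$mirnaId)),
      "miRNAs,", length(unique(tolower(e$geneSymbol))), "genes\n")
  if (nrow(e)) print(table(factor(e$evidence, .evidenceLevels)))
})

setMethod("length", "TargetMap", function(x) nrow(x@edges))
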