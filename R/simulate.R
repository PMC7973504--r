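# Synthetic-data generators.
#
# One master seed per SimConfig; each generator derives fixed per-stage
# substream seeds (seed + small offsets) so stages are independently
# reproducible. All raw intensities are log-normal: within-group log2 sd is
# sqrt(log(1 + cv^2)) / log(2), the exact log-normal relation, so realized
# raw-scale CVs equal the configured cv up to Monte-Carlo error.

.log2SdFromCv <- function(cv) sqrt(log1p(cv^2)) / log(2)

.simulateIntensity <- function(config, idPrefix, geneNames = FALSE) {
  validObject(config)
  n <- config@nFeatures
  k <- config@nPerGroup
  sdw <- .log2SdFromCv(config@cv)

  # substream 1: feature background and planted effects
  set.seed(config@seed)
  mu <- rnorm(n, config@baseLog2Mean, config@baseLog2Sd)
  nChanged <- round(config@deFraction * n)
  isChanged <- rep(FALSE, n)
  if (nChanged > 0) isChanged[sample.int(n, nChanged)] <- TRUE
  mag <- runif(n, config@log2fcRange[1], config@log2fcRange[2])
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  trueLog2FC <- ifelse(isChanged, sgn * mag, 0)

  # substream 2: within-group noise
  set.seed(config@seed + 1L)
  centre <- cbind(matrix(mu, n, k), matrix(mu + trueLog2FC, n, k))
  log2mat <- centre + matrix(rnorm(n * 2L * k, 0, sdw), n, 2L * k)

  # substream 3: logistic-in-intensity MNAR censoring
  set.seed(config@seed + 2L)
  if (config@mnarCensorQuantile > 0 && config@mnarSteepness > 0) {
    anchor <- quantile(log2mat, config@mnarCensorQuantile, names = FALSE)
    pmiss <- plogis(-(log2mat - anchor) * config@mnarSteepness)
    miss <- matrix(runif(n * 2L * k) < pmiss, n, 2L * k)
  } else {
    miss <- matrix(FALSE, n, 2L * k)
  }

  raw <- 2^log2mat
  raw[miss] <- NA_real_
  featureId <- sprintf("%s%04d", idPrefix, seq_len(n))
  rownames(raw) <- featureId
  colnames(raw) <- paste0(rep(config@groupNames, each = k), "_", seq_len(k))
  rd <- DataFrame(featureId = featureId,
                  isChanged = isChanged, trueLog2FC = trueLog2FC)
  if (geneNames) {
    rd$geneName <- sprintf("GENE%04d", seq_len(n))
    rd <- rd[, c("featureId", "geneName", "isChanged", "trueLog2FC")]
  }
  IntensityExperiment(raw, rep(config@groupNames, each = k), rowData = rd)
}

#' Simulate an LFQ proteomics screen
#'
#' Generates a raw-scale protein intensity matrix with the statistical
#' structure the downstream pipeline assumes: log-normal intensities with a
#' configured within-group CV, a planted fraction of true changes applied to
#' the second (treatment) group, and intensity-dependent (MNAR) missingness
#' following a logistic left-censoring rule. Ground truth is stored in
#' `rowData` and retrievable with [simTruth()].
#'
#' @param config a [SimConfig-class] (proteomics defaults: `nPerGroup = 5`).
#' @return an [IntensityExperiment-class] whose `rowData` carries
#'   `featureId`, `geneName`, `isChanged`, `trueLog2FC`.
#' @examples
#' sim <- simulateLFQ(simConfig(nFeatures = 200, seed = 3))
#' simTruth(sim)[1:3, ]
#' @export
simulateLFQ <- function(config = simConfig()) {
  .simulateIntensity(config, "P", geneNames = TRUE)
}

#' Simulate a miRNA array screen
#'
#' As [simulateLFQ()] but for the array arm of the design: the usual
#' configuration uses 3 replicates per group and no missingness
#' (`mnarCensorQuantile = 0`), since array matrices are complete.
#'
#' @param config a [SimConfig-class].
#' @return an [IntensityExperiment-class] with simulated truth in `rowData`.
#' @export
simulateMirna <- function(config = simConfig(nPerGroup = 3,
                                             mnarCensorQuantile = 0,
                                             cv = 0.2)) {
  .simulateIntensity(config, "sim-miR-", geneNames = FALSE)
}

#' Simulate a miRNA-to-gene target map with planted inverse pairs
#'
#' Builds a [TargetMap-class] containing exactly `plantedPairs` edges that
#' link a truly changed miRNA to a truly changed protein of *opposite*
#' direction (so a perfectly powered pipeline must recover them through the
#' inverse-expression filter), plus `decoyPairs` edges drawn uniformly from
#' the remaining (miRNA, gene) combinations.
#'
#' @param mirnaTruth,protTruth `simTruth()` tables of [simulateMirna()] and
#'   [simulateLFQ()] output; the protein table must carry `geneName`.
#' @param plantedPairs,decoyPairs edge counts.
#' @param seed RNG seed.
#' @return a `TargetMap`; `metadata(targetEdges(map))$planted` is a logical
#'   vector marking the planted edges.
#' @export
simulateTargetMap <- function(mirnaTruth, protTruth, plantedPairs = 5,
                              decoyPairs = 20, seed = 1L) {
  mirnaTruth <- DataFrame(mirnaTruth)
  protTruth <- DataFrame(protTruth)
  stopifnot("geneName" %in% colnames(protTruth))
  set.seed(as.integer(seed))
  mChanged <- which(mirnaTruth$isChanged)
  pChanged <- which(protTruth$isChanged)
  combos <- expand.grid(m = mChanged, p = pChanged)
  opposite <- sign(mirnaTruth$trueLog2FC[combos$m]) !=
    sign(protTruth$trueLog2FC[combos$p])
  combos <- combos[opposite, , drop = FALSE]
  if (plantedPairs > nrow(combos))
    stop("plantedPairs exceeds the ", nrow(combos),
         " available opposite-direction changed combinations")
  planted <- combos[sample.int(nrow(combos), plantedPairs), , drop = FALSE]
  edges <- data.frame(
    mirnaId = mirnaTruth$featureId[planted$m],
    geneSymbol = protTruth$geneName[planted$p],
    stringsAsFactors = FALSE)
  isPlanted <- rep(TRUE, nrow(edges))
  if (decoyPairs > 0) {
    all <- expand.grid(m = seq_len(nrow(mirnaTruth)),
                       p = seq_len(nrow(protTruth)))
    key <- paste(mirnaTruth$featureId[all$m], protTruth$geneName[all$p])
    taken <- paste(edges$mirnaId, edges$geneSymbol)
    pool <- which(!key %in% taken)
    dec <- all[sample(pool, min(decoyPairs, length(pool))), , drop = FALSE]
    edges <- rbind(edges, data.frame(
      mirnaId = mirnaTruth$featureId[dec$m],
      geneSymbol = protTruth$geneName[dec$p], stringsAsFactors = FALSE))
    isPlanted <- c(isPlanted, rep(FALSE, nrow(dec)))
  }
  edges$evidence <- sample(.evidenceLevels, nrow(edges), replace = TRUE)
  map <- TargetMap(edges)
  metadata(map@edges)$planted <- isPlanted
  map
}

#' Simulate a qPCR CT table
#'
#' Emulates the CT-value structure of a reference-normalized qPCR design:
#' per sample, the reference gene cycles around `referenceCt`, and the
#' target sits `baseDeltaCt - log2(foldChange)` cycles above the reference
#' (so lower expression means later amplification), each reading perturbed
#' by Gaussian noise of sd `noiseSd` cycles.
#'
#' @param groups character vector of group names; the first is the
#'   calibrator (its fold change is forced to 1).
#' @param trueFoldChanges per-group expression fold changes relative to the
#'   calibrator; recycled/na-filled to `length(groups)`.
#' @param nPerGroup samples per group.
#' @param target,reference assay names (default reference `"RNU6B"`).
#' @param referenceCt,baseDeltaCt cycle-scale location parameters.
#' @param noiseSd Gaussian CT noise, in cycles.
#' @param seed RNG seed.
#' @return a CT table `data.frame` with columns `sampleId`, `group`,
#'   `target`, `ct` (long format; reference rows included).
#' @export
simulateCTTable <- function(groups = c("UNT", "FAC"),
                            trueFoldChanges = c(1, 1),
                            nPerGroup = 3, target = "miR-432-5p",
                            reference = "RNU6B", referenceCt = 20,
                            baseDeltaCt = 5, noiseSd = 0.2, seed = 1L) {
  stopifnot(length(trueFoldChanges) == length(groups),
            all(trueFoldChanges > 0), noiseSd >= 0)
  trueFoldChanges[1] <- 1
  set.seed(as.integer(seed))
  rows <- do.call(rbind, lapply(seq_along(groups), function(g) {
    sampleId <- sprintf("%s_%d", groups[g], seq_len(nPerGroup))
    refCt <- referenceCt + rnorm(nPerGroup, 0, noiseSd)
    tgtCt <- refCt + baseDeltaCt - log2(trueFoldChanges[g]) +
      rnorm(nPerGroup, 0, noiseSd)
    data.frame(sampleId = rep(sampleId, 2L),
               group = groups[g],
               target = rep(c(reference, target), each = nPerGroup),
               ct = c(refCt, tgtCt), stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Simulate a promoter window with a planted, possibly degenerate motif
#'
#' Generates a uniform-random ACGT background of the requested length and
#' overwrites it at `plantPosition` (0-based) with a copy of `motif` carrying
#' exactly `nMismatches` substitutions at distinct positions.
#'
#' @param length window length in bp (must be at least `nchar(motif)`).
#' @param motif uppercase ACGT string to plant.
#' @param plantPosition 0-based offset of the planted copy.
#' @param nMismatches number of positions of the planted copy to mutate.
#' @param seed RNG seed.
#' @return a [Biostrings::DNAString]; `metadata`-free, the planted position
#'   is the caller's ground truth.
#' @export
simulatePromoter <- function(length, motif, plantPosition = 0,
                             nMismatches = 0, seed = 1L) {
  w <- nchar(motif)
  if (length < w)
    stop("window length (", length, ") is shorter than the motif (", w, ")")
  if (plantPosition < 0 || plantPosition + w > length)
    stop("plantPosition puts the motif outside the window")
  if (nMismatches < 0 || nMismatches > w)
    stop("nMismatches must be between 0 and the motif length")
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must be an uppercase ACGT string")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  bg <- sample(bases, length, replace = TRUE)
  planted <- strsplit(motif, "")[[1]]
  if (nMismatches > 0) {
    at <- sample.int(w, nMismatches)
    for (i in at) planted[i] <- sample(setdiff(bases, planted[i]), 1L)
  }
  bg[plantPosition + seq_len(w)] <- planted
  Biostrings::DNAString(paste(bg, collapse = ""))
}
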