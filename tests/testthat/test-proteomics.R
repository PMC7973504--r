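test_that("cleaning drops flagged rows and logs the reasons", {
  df <- toyProteinGroups(10, nReverse = 2, nContaminant = 1, nSiteOnly = 1)
  out <- cleanProteinGroups(df)
  expect_equal(nrow(out), 6)
  log <- attr(out, "filterLog")
  expect_equal(log$nReverse, 2)
  expect_equal(log$nContaminant, 1)
  expect_equal(log$nSiteOnly, 1)
  # unflagged input passes through row-identically
  df0 <- toyProteinGroups(5)
  expect_equal(cleanProteinGroups(df0)[["Protein IDs"]],
               df0[["Protein IDs"]])
  # zeros become missing
  df0[["LFQ intensity UNT_1"]][2] <- 0
  expect_true(is.na(cleanProteinGroups(df0)[["LFQ intensity UNT_1"]][2]))
  expect_error(readProteinGroups(textConnection("x\ty")), "required")
})

test_that("protein-groups writer and reader round-trip bit-exactly", {
  sim <- simulateLFQ(simConfig(nFeatures = 40, seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeProteinGroups(sim, f)
  back <- asIntensityExperiment(
    cleanProteinGroups(readProteinGroups(f)),
    list(UNT = paste0("UNT_", 1:5), FAC = paste0("FAC_", 1:5)))
  expect_identical(unname(intensities(back)), unname(intensities(sim)))
})

test_that("valid-value filter implements the any-group and both-group rules", {
  m <- rbind(
    c(1, 1, 1, 1, 1, NA, NA, NA, NA, NA),   # 5/5 and 0/5
    c(1, 1, NA, NA, NA, 1, 1, NA, NA, NA),  # 2/5 and 2/5
    c(1, 1, 1, NA, NA, 1, 1, 1, NA, NA))    # 3/5 and 3/5
  rownames(m) <- c("a", "b", "c")
  colnames(m) <- paste0(rep(c("U", "F"), each = 5), 1:5)
  x <- IntensityExperiment(m, rep(c("U", "F"), each = 5))
  expect_equal(rownames(filterValidValues(x, 3, "any")), c("a", "c"))
  expect_equal(rownames(filterValidValues(x, 3, "both")), "c")
  expect_error(filterValidValues(x, 6), "smallest group size")
  # retained set equals a brute-force recount of the mask on simulated data
  sim <- simulateLFQ(simConfig(nFeatures = 300, mnarCensorQuantile = 0.3,
                               mnarSteepness = 1, seed = 5))
  kept <- rownames(filterValidValues(sim, 3, "any"))
  obs <- !is.na(intensities(sim))
  g <- sampleGroups(sim)
  brute <- rownames(sim)[rowSums(obs[, g == levels(g)[1]]) >= 3 |
                           rowSums(obs[, g == levels(g)[2]]) >= 3]
  expect_identical(kept, brute)
})

test_that("MNAR imputation draws from the downshifted distribution and
           leaves observed cells untouched", {
  # complete matrix: bit-exact identity
  m <- matrix(rnorm(50, 25, 2), 10, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  expect_identical(imputeMNAR(m, seed = 1), m)
  # moments of 1e4 imputed entries in one column
  set.seed(42)
  col <- c(rnorm(10000, 25, 2), rep(NA_real_, 10000))
  mat <- matrix(col, ncol = 1, dimnames = list(NULL, "s1"))
  obsM <- mean(col, na.rm = TRUE)
  obsS <- sd(col, na.rm = TRUE)
  imp <- imputeMNAR(mat, width = 0.3, downshift = 1.8, seed = 7)
  expect_identical(imp[1:10000, 1], col[1:10000])
  vals <- imp[10001:20000, 1]
  expect_lt(abs(mean(vals) - (obsM - 1.8 * obsS)),
            3 * 0.3 * obsS / sqrt(10000))
  expect_lt(abs(sd(vals) - 0.3 * obsS),
            3 * 0.3 * obsS / sqrt(2 * (10000 - 1)))
  # zero downshift, vanishing width: imputed values collapse to the mean
  tiny <- imputeMNAR(mat, width = 1e-9, downshift = 0, seed = 7)
  expect_lt(max(abs(tiny[10001:20000, 1] - obsM)), 1e-6)
  # undefined sd
  bad <- matrix(c(1, rep(NA_real_, 4)), ncol = 1,
                dimnames = list(NULL, "s1"))
  expect_error(imputeMNAR(bad), "fewer than 2 observed")
})

test_that("Welch test matches the textbook formulas and behaves monotonely", {
  a <- c(10.1, 10.4, 9.9, 10.2, 10.0)
  b <- c(12.0, 12.3, 11.8, 12.1, 12.2)
  got <- welchTest(a, b)
  ora <- welchOracle(a, b)
  expect_equal(got$t, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  ident <- welchTest(1:5, 1:5)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  # inflating the separation at fixed spread strictly decreases p
  ps <- vapply(c(0.5, 1, 2, 4), function(d) welchTest(a, a + d)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # zero-variance conventions
  expect_equal(welchTest(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welchTest(c(1, 1), c(2, 2))$p, 0)
})

test_that("z-scores standardize exactly and are affine invariant", {
  expect_equal(computeZScores(c(-1, 0, 1)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 3, 2)
  z <- computeZScores(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(computeZScores(5 * x - 2), z)
  expect_error(computeZScores(rep(1, 5)), "zero spread")
  expect_error(computeZScores(c(1, NA, Inf)), "at least 2")
})

test_that("tier classification applies the combined filter with a subset chain", {
  rec <- data.frame(pRaw = c(0.04, 0.04, 0.04, 0.2, 0.01),
                    z = c(1.5, 0.5, 1.5, 3, -2),
                    ratio = c(3, 10, 5, 8, 0.2))
  out <- classifyTargets(rec)
  expect_equal(as.character(out$tier),
               c("differential", "not_significant", "top",
                 "not_significant", "top"))
  # chain on random tables
  set.seed(2)
  rnd <- data.frame(pRaw = runif(500), z = rnorm(500, 0, 2),
                    ratio = 2^rnorm(500, 0, 2))
  cls <- classifyTargets(rnd)
  expect_true(all(cls$top <= cls$differential))
  expect_true(all(cls$differential <= cls$significant))
  expect_true(all(cls$significant <= (cls$pRaw < 0.05)))
})

test_that("CV summary matches a hand computation and the generator", {
  m <- rbind(c(10, 12, 14, 20, 20, 20),
             c(5, 5, 5, 8, 10, 12))
  colnames(m) <- paste0(rep(c("U", "F"), each = 3), 1:3)
  x <- IntensityExperiment(m, rep(c("U", "F"), each = 3))
  got <- cvSummary(x)
  cvs <- function(v) sd(v) / mean(v)
  expect_equal(got$meanCV[got$group == "U"],
               100 * mean(c(cvs(m[1, 1:3]), cvs(m[2, 1:3]))),
               tolerance = 1e-12)
  expect_equal(got$medianCV[got$group == "F"],
               100 * median(c(cvs(m[1, 4:6]), cvs(m[2, 4:6]))),
               tolerance = 1e-12)
  const <- IntensityExperiment(matrix(7, 3, 6, dimnames = list(
    NULL, colnames(m))), rep(c("U", "F"), each = 3))
  expect_true(all(cvSummary(const)$meanCV == 0))
  sim <- simulateLFQ(simConfig(nFeatures = 2000, cv = 0.25,
                               deFraction = 0, mnarCensorQuantile = 0,
                               seed = 16))
  expect_true(all(abs(cvSummary(sim)$meanCV - 25) < 2))
})

test_that("null simulation is calibrated through the full pipeline", {
  sim <- simulateLFQ(simConfig(nFeatures = 2000, deFraction = 0,
                               mnarCensorQuantile = 0, seed = 12))
  de <- proteinDE(sim, seed = 12)
  frac <- mean(de$pRaw < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_true(all(de$significant <= (de$pRaw < 0.05)))
})

test_that("pipeline recovers planted fourfold changes with high sensitivity", {
  cfg <- simConfig(nFeatures = 2000, deFraction = 0.1,
                   log2fcRange = c(2, 2), cv = 0.2,
                   mnarCensorQuantile = 0.1, mnarSteepness = 2, seed = 13)
  sim <- simulateLFQ(cfg)
  expect_lt(abs(mean(is.na(intensities(sim))) - 0.1), 0.05)
  de <- proteinDE(sim, seed = 13)
  tr <- simTruth(sim)
  truth <- tr$isChanged[match(rownames(de), tr$featureId)]
  sens <- mean(de$differential[truth])
  expect_gte(sens, 0.9)
  # realized false-discovery proportion is reported, not bounded
  fdp <- sum(de$differential & !truth) / max(1, sum(de$differential))
  expect_true(is.finite(fdp))
})
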