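test_that("identical configuration reproduces bit-identical output", {
  cfg <- simConfig(nFeatures = 100, seed = 7)
  expect_identical(intensities(simulateLFQ(cfg)),
                   intensities(simulateLFQ(cfg)))
  cfgM <- simConfig(nFeatures = 50, nPerGroup = 3, mnarCensorQuantile = 0,
                    seed = 8)
  expect_identical(intensities(simulateMirna(cfgM)),
                   intensities(simulateMirna(cfgM)))
  expect_identical(
    as.character(simulatePromoter(100, "GACAAGATA", 10, 2, seed = 3)),
    as.character(simulatePromoter(100, "GACAAGATA", 10, 2, seed = 3)))
  ct <- simulateCTTable(noiseSd = 0.3, seed = 5)
  expect_identical(ct, simulateCTTable(noiseSd = 0.3, seed = 5))
})

test_that("null configuration yields complete data with equal group means", {
  cfg <- simConfig(nFeatures = 500, deFraction = 0,
                   mnarCensorQuantile = 0, seed = 2)
  sim <- simulateLFQ(cfg)
  m <- intensities(sim)
  expect_false(anyNA(m))
  expect_true(all(!simTruth(sim)$isChanged))
  expect_true(all(simTruth(sim)$trueLog2FC == 0))
  g <- sampleGroups(sim)
  diff <- rowMeans(log2(m[, g == "FAC"])) - rowMeans(log2(m[, g == "UNT"]))
  sdw <- sqrt(log1p(cfg@cv^2)) / log(2)
  # mean difference over 500 null features: se = sdw * sqrt(2/5) / sqrt(500)
  expect_lt(abs(mean(diff)), 3 * sdw * sqrt(2 / 5) / sqrt(500))
})

test_that("realized per-group CV matches the configured CV", {
  sim <- simulateLFQ(simConfig(nFeatures = 2000, cv = 0.196,
                               deFraction = 0, mnarCensorQuantile = 0,
                               seed = 4))
  cv <- cvSummary(sim)
  expect_true(all(abs(cv$meanCV / 100 - 0.196) < 0.02))
})

test_that("MNAR missingness matches numerical integration of the logistic rule", {
  cfg <- simConfig(nFeatures = 2000, deFraction = 0,
                   mnarCensorQuantile = 0.1, mnarSteepness = 2, seed = 11)
  sim <- simulateLFQ(cfg)
  m <- intensities(sim)
  rate <- mean(is.na(m))
  sdw <- sqrt(log1p(cfg@cv^2)) / log(2)
  sdt <- sqrt(cfg@baseLog2Sd^2 + sdw^2)
  anchor <- qnorm(0.1, cfg@baseLog2Mean, sdt)
  expected <- integrate(function(x)
    plogis(-(x - anchor) * cfg@mnarSteepness) *
      dnorm(x, cfg@baseLog2Mean, sdt),
    cfg@baseLog2Mean - 12 * sdt, cfg@baseLog2Mean + 12 * sdt)$value
  se <- sqrt(expected * (1 - expected) / length(m))
  expect_lt(abs(rate - expected), 3 * se)
})

test_that("missing entries concentrate at low intensity", {
  sim <- simulateLFQ(simConfig(nFeatures = 1000, deFraction = 0,
                               mnarCensorQuantile = 0.2,
                               mnarSteepness = 5, seed = 9))
  # reconstruct the uncensored matrix from the same config with censoring off
  full <- intensities(simulateLFQ(simConfig(nFeatures = 1000,
                                            deFraction = 0,
                                            mnarCensorQuantile = 0,
                                            seed = 9)))
  miss <- is.na(intensities(sim))
  expect_gt(sum(miss), 0)
  expect_lt(mean(log2(full[miss])), mean(log2(full[!miss])))
})

test_that("null miRNA simulation gives uniform t-test p-values", {
  sim <- simulateMirna(simConfig(nFeatures = 2000, nPerGroup = 3,
                                 deFraction = 0, mnarCensorQuantile = 0,
                                 seed = 15))
  p <- mirnaDETest(sim)$pRaw
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted 100-fold effects are recovered from the generated matrix", {
  cfg <- simConfig(nFeatures = 200, nPerGroup = 3, cv = 0.2,
                   deFraction = 1, log2fcRange = log2(c(100, 100)),
                   mnarCensorQuantile = 0, seed = 14)
  sim <- simulateMirna(cfg)
  tr <- simTruth(sim)
  de <- mirnaDETest(sim)
  down <- tr$trueLog2FC < 0
  recovered <- 1 / exp(mean(log(de$ratio[down])))  # geometric mean fold
  expect_lt(abs(recovered - 100) / 100, 0.2)
  up <- exp(mean(log(de$ratio[!down])))
  expect_lt(abs(up - 100) / 100, 0.2)
})

test_that("target-map simulation plants inverse pairs and respects feasibility", {
  prot <- simulateLFQ(simConfig(nFeatures = 100, deFraction = 0.2,
                                mnarCensorQuantile = 0, seed = 6))
  mir <- simulateMirna(simConfig(nFeatures = 60, nPerGroup = 3,
                                 deFraction = 0.2, mnarCensorQuantile = 0,
                                 seed = 7))
  mt <- simTruth(mir)
  pt <- simTruth(prot)
  map <- simulateTargetMap(mt, pt, plantedPairs = 5, decoyPairs = 10,
                           seed = 1)
  edges <- as.data.frame(targetEdges(map))
  expect_equal(nrow(edges), 15)
  planted <- S4Vectors::metadata(targetEdges(map))$planted
  expect_equal(sum(planted), 5)
  for (i in which(planted)) {
    mfc <- mt$trueLog2FC[match(edges$mirnaId[i], mt$featureId)]
    pfc <- pt$trueLog2FC[match(edges$geneSymbol[i], pt$geneName)]
    expect_true(sign(mfc) != sign(pfc))
  }
  expect_equal(length(simulateTargetMap(mt, pt, 0, 0, seed = 1)), 0)
  expect_error(simulateTargetMap(mt, pt, plantedPairs = 1e6, seed = 1),
               "exceeds")
})

test_that("CT simulation reproduces planted folds analytically at zero noise", {
  ct1 <- simulateCTTable(trueFoldChanges = c(1, 1), noiseSd = 0, seed = 2)
  res1 <- ddctFoldChange(ct1, "miR-432-5p", "FAC", "UNT")
  expect_equal(res1$ddCt, 0)
  expect_equal(res1$foldChange, 1)
  ct16 <- simulateCTTable(trueFoldChanges = c(1, 1 / 16), noiseSd = 0,
                          seed = 2)
  expect_equal(ddctFoldChange(ct16, "miR-432-5p", "FAC",
                              "UNT")$foldChange, 0.0625)
})

test_that("noisy CT estimates stay within the closed-form log-normal band", {
  # mean ddCT error is Gaussian: sd = noiseSd * 2 / sqrt(n) per group pair
  noise <- 0.2
  n <- 3
  ct <- simulateCTTable(trueFoldChanges = c(1, 1 / 100), noiseSd = noise,
                        nPerGroup = n, seed = 10)
  fold <- ddctFoldChange(ct, "miR-432-5p", "FAC", "UNT")$foldChange
  # ddCT = mean of n iid diffs each with sd sqrt(2)*noise, two groups
  sdDdct <- sqrt(2) * noise * sqrt(2 / n)
  expect_lt(abs(log2(fold) - log2(1 / 100)), 3 * sdDdct)
})

test_that("promoter simulation plants motifs with the requested degeneracy", {
  motif <- "GACAAGATA"
  seq0 <- simulatePromoter(400, motif, plantPosition = 120,
                           nMismatches = 0, seed = 5)
  hit <- scanMotifs(seq0, c(n_terminal = motif), topK = 1)
  expect_equal(hit$position, 120)
  expect_equal(hit$matches, 9)
  seq4 <- simulatePromoter(400, motif, plantPosition = 120,
                           nMismatches = 4, seed = 5)
  at <- scanMotifs(seq4, c(n_terminal = motif), topK = 400)
  expect_equal(at$matches[at$position == 120], 5)
  expect_error(simulatePromoter(5, motif), "shorter than the motif")
  expect_error(simulatePromoter(100, motif, plantPosition = 95),
               "outside the window")
})
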