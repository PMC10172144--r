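test_that("strip construction follows the interdigitated layout", {
  strip <- generateStrip(20)
  expect_equal(length(axisLine(strip)), 120L)
  labs <- as.character(regionLabels(strip))[axisLine(strip)]
  expect_equal(unique(labs),
               c("foot", "inter_superior", "hand", "inter_middle",
                 "mouth", "inter_inferior"))
  ## axis positions are consecutive integers 0..L-1
  expect_equal(axisPositions(strip)[axisLine(strip)], 0:119)
  ## degenerate config refused
  expect_error(generateStrip(c(foot = 0L, inter_superior = 10L, hand = 10L,
                               inter_middle = 10L, mouth = 10L,
                               inter_inferior = 10L)),
               "positive vertex count")
  ## same parameters -> identical geometry
  expect_identical(generateStrip(12), generateStrip(12))
})

test_that("rest generation is the deterministic signal model at zero noise", {
  strip <- tinyStrip()
  ## all inter regions share the scan latent; zero lags everywhere
  truth <- syntheticTruth(strip, noiseSd = 0,
                          delays = setNames(rep(0, nlevels(regionLabels(strip))),
                                            levels(regionLabels(strip))),
                          seed = 9)
  run <- generateRestRun(strip, truth, nFrames = 128, tr = 1.1, seed = 9)
  m <- SummarizedExperiment::assay(run, "bold")
  lab <- as.character(regionLabels(strip))
  iSup <- which(lab == "inter_superior")
  iMid <- which(lab == "inter_middle")
  ## same latent, same (zero) lag, zero noise -> identical time courses
  expect_equal(m[iSup[1], ], m[iMid[1], ], tolerance = 1e-12)
  ## different latent -> different
  expect_gt(max(abs(m[iSup[1], ] - m[which(lab == "foot")[1], ])), 0.1)
})

test_that("rest runs are reproducible under a fixed seed", {
  strip <- tinyStrip()
  truth <- syntheticTruth(strip, noiseSd = 0.7, seed = 4)
  r1 <- generateRestRun(strip, truth, nFrames = 96, tr = 1.2, seed = 21)
  r2 <- generateRestRun(strip, truth, nFrames = 96, tr = 1.2, seed = 21)
  expect_identical(SummarizedExperiment::assay(r1),
                   SummarizedExperiment::assay(r2))
  expect_error(generateRestRun(strip, truth, nFrames = 32, tr = 1.2),
               "at least 64")
})

test_that("injected lag appears at the brute-force cross-correlation peak", {
  strip <- generateStrip(4, offAxis = c(CON = 4L))
  delays <- c(foot = 0, inter_superior = 0, hand = 0, inter_middle = 0,
              mouth = 0, inter_inferior = 0, CON = 1.0)
  ## CON shares the inter latent by default, so the pair is well correlated
  truth <- syntheticTruth(strip, delays = delays, noiseSd = 0, seed = 3)
  run <- generateRestRun(strip, truth, nFrames = 512, tr = 0.5, seed = 3)
  m <- SummarizedExperiment::assay(run)
  lab <- as.character(regionLabels(strip))
  inter <- colMeans(m[lab == "inter_superior", , drop = FALSE])
  con <- colMeans(m[lab == "CON", , drop = FALSE])
  cc <- bruteCCF(inter, con, 10)
  ## CON lags inter by 1.0 s = 2 frames at tr 0.5
  expect_equal(which.max(cc) - 11L, 2L)
})

test_that("task responses follow the injected spatial profile and design", {
  ## the battery block structure: 2.2 s cue + 12 movements at 1.1 s
  d <- blockBattery(c("toes", "hand"), blocksPerCondition = 1L,
                    restBlocks = 0L)
  expect_equal(unique(d@events$duration), 15.4)
  strip <- motorOnlyStrip()
  pk <- list(toes = c(a1 = 2, b1 = 30, c1 = 5),
             hand = c(a1 = 0, b1 = 40, c1 = 5))
  truth <- syntheticTruth(strip, peakParams = pk, noiseSd = 0, seed = 1)
  run <- generateTaskRun(strip, truth, d, tr = 2.2, seed = 1)
  X <- buildDesignMatrix(d, 2.2, ncol(run))
  am <- fitGLM(run, X)
  pos <- axisPositions(strip)
  ## noiseless betas equal the true profile; zero-amplitude condition -> 0
  expect_equal(unname(activationBeta(am)[, "toes"]),
               gaussProfile(pk$toes, pos), tolerance = 1e-8)
  expect_equal(max(abs(activationBeta(am)[, "hand"])), 0, tolerance = 1e-10)
  ## closed loop: fit recovers the injected centre at machine-level accuracy
  prof <- axisProfile(activationBeta(am)[, "toes"], pos)
  fits <- fitPeakModels(prof)
  expect_lt(abs(fits$onePeak@params[["b1"]] - 30), 1e-6)
  ## design extending past the run end is refused
  expect_error(taskDesign(data.frame(condition = "x", onset = 50,
                                     duration = 20), runLength = 60),
               "past the end")
})

test_that("structural maps honour region effects and myelin normalization", {
  strip <- tinyStrip()
  eff <- defaultStructuralEffects()
  eff$sd <- 0
  maps <- generateStructuralMaps(strip, eff, seed = 2)
  expect_equal(unique(maps$thickness[maps$region == "inter_middle"]), 2.3)
  expect_equal(unique(maps$thickness[maps$region == "foot"]), 2.7)
  ## normalized myelin averages exactly 1 over the motor strip
  pg <- maps$region %in% motorRegions()
  expect_equal(mean(maps$myelinNorm[pg]), 1, tolerance = 1e-12)
  ## negative sd refused
  bad <- eff; bad$sd[1] <- -1
  expect_error(generateStructuralMaps(strip, bad), "negative sd")
})

test_that("structural sampling matches its distribution at moderate n", {
  strip <- generateStrip(100, offAxis = c(CON = 0L, S1_adjacent = 0L,
                                          background = 0L))
  maps <- generateStructuralMaps(strip, seed = 8)
  eff <- defaultStructuralEffects()
  for (r in c("foot", "inter_middle")) {
    want <- eff$mean[eff$region == r & eff$metric == "thickness"]
    got <- mean(maps$thickness[maps$region == r])
    expect_lt(abs(got - want), 3 * 0.15 / sqrt(100))
  }
})
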