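test_that("design matrix sampling and HRF convolution are exact", {
  ## a 15.4 s block at tr 2.2 spans 7 frames before convolution
  d <- taskDesign(data.frame(condition = "m", onset = 0, duration = 15.4),
                  runLength = 110)
  nf <- 50L
  times <- (0:(nf - 1)) * 2.2
  expect_equal(sum(times >= 0 & times < 15.4), 7L)
  ## convolution of a unit impulse reproduces the HRF samples exactly
  dImp <- taskDesign(data.frame(condition = "e", onset = 0, duration = 0),
                     runLength = 110)
  X <- buildDesignMatrix(dImp, 2.2, nf, intercept = FALSE)
  hrf <- doubleGammaHRF(seq(0, 32, by = 2.2))
  expect_equal(unname(X[seq_along(hrf), "e"]), hrf, tolerance = 1e-12)
  ## empty design gives an intercept-only matrix
  dEmpty <- taskDesign(data.frame(condition = character(),
                                  onset = numeric(), duration = numeric()),
                       runLength = 110)
  X0 <- buildDesignMatrix(dEmpty, 2.2, nf)
  expect_equal(colnames(X0), "(Intercept)")
})

test_that("GLM betas equal the normal-equation solve and residuals are orthogonal", {
  set.seed(17)
  nf <- 80L
  d <- taskDesign(data.frame(condition = c("a", "b"),
                             onset = c(10, 60), duration = c(15.4, 15.4)),
                  runLength = 176)
  X <- buildDesignMatrix(d, 2.2, nf)
  Y <- matrix(rnorm(nf * 30), nf, 30)
  am <- fitGLM(t(Y), X)
  betaRef <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(t(activationBeta(am))),
               unname(betaRef[c("a", "b"), ]), tolerance = 1e-12)
  res <- Y - X %*% betaRef
  expect_lt(max(abs(crossprod(X, res))), 1e-9)
  ## rank deficiency is reported with the offending column
  Xbad <- cbind(X, a2 = X[, "a"])
  attr(Xbad, "conditions") <- c(attr(X, "conditions"), "a2")
  expect_error(fitGLM(t(Y), Xbad), "collinear")
})

test_that("noiseless injected effects are recovered exactly", {
  strip <- motorOnlyStrip()
  pk <- list(move = c(a1 = 2, b1 = 25, c1 = 6))
  truth <- syntheticTruth(strip, peakParams = pk, noiseSd = 0, seed = 3)
  d <- blockBattery("move", blocksPerCondition = 2L, restBlocks = 1L)
  run <- generateTaskRun(strip, truth, d, tr = 2.2, seed = 3)
  X <- buildDesignMatrix(d, 2.2, ncol(run))
  am <- fitGLM(run, X)
  pos <- axisPositions(strip)
  expect_equal(unname(activationBeta(am)[, "move"]),
               gaussProfile(pk$move, pos), tolerance = 1e-10)
})

test_that("second level tests run betas against zero with edge conventions", {
  mkMap <- function(betas) {
    b <- cbind(m = betas)
    new("ActivationMap", beta = b, tstat = b * 0, z = b * 0, df = 10,
        level = "run", degenerate = b * 0 > 1)
  }
  ## betas {1, -1} -> t = 0, Z = 0
  subj <- secondLevel(list(mkMap(1), mkMap(-1)))
  expect_equal(unname(activationZ(subj)[1, 1]), 0)
  ## equal non-zero betas -> degenerate, excluded
  subj2 <- secondLevel(list(mkMap(2), mkMap(2), mkMap(2)))
  expect_true(subj2@degenerate[1, 1])
  expect_true(is.na(activationZ(subj2)[1, 1]))
  expect_error(secondLevel(list(mkMap(1))), "at least 2")
  ## simulated effect: mean Z near the analytic one-sample expectation
  set.seed(23)
  R <- 20L
  zed <- replicate(200, {
    maps <- lapply(seq_len(R), function(i) mkMap(rnorm(1, 1, 1)))
    activationZ(secondLevel(maps))[1, 1]
  })
  ## non-central t with ncp = sqrt(R) * d, d = 1
  tSamples <- replicate(2000, {
    x <- rnorm(R, 1, 1); mean(x) / (sd(x) / sqrt(R))
  })
  want <- mean(sign(tSamples) * qnorm(pt(abs(tSamples), R - 1,
                                         lower.tail = FALSE, log.p = TRUE),
                                      lower.tail = FALSE, log.p = TRUE))
  expect_lt(abs(mean(zed) - want), 3 * sd(zed) / sqrt(200) + 3 *
              sd(tSamples) / sqrt(2000))
})

test_that("planning-versus-execution is a vertexwise paired t-test", {
  set.seed(29)
  nv <- 40L; R <- 6L
  mk <- function(p, e) {
    b <- cbind(planning = p, execution = e)
    new("ActivationMap", beta = b, tstat = b * 0, z = b * 0, df = 5,
        level = "run", degenerate = b * 0 > 1)
  }
  plans <- matrix(rnorm(nv * R, 1), nv)
  execs <- matrix(rnorm(nv * R, 0.5), nv)
  maps <- lapply(seq_len(R), function(r) mk(plans[, r], execs[, r]))
  pe <- planningVsExecution(maps)
  ## oracle: paired t on each vertex
  for (v in c(1L, 17L)) {
    ref <- t.test(plans[v, ], execs[v, ], paired = TRUE)
    expect_equal(unname(activationT(pe)[v, 1]), unname(ref$statistic),
                 tolerance = 1e-12)
  }
  ## identical phases give a zero map
  same <- lapply(seq_len(R), function(r) mk(plans[, r], plans[, r]))
  expect_equal(max(abs(activationZ(planningVsExecution(same)))), 0)
  expect_error(planningVsExecution(maps[1]), "at least 2")
})

test_that("axis smoothing is mass-conserving with a correct kernel", {
  v <- rnorm(60)
  expect_identical(smoothMap(v, 0), v)
  expect_equal(smoothMap(rep(3, 60), 2.55), rep(3, 60), tolerance = 1e-12)
  expect_equal(mean(smoothMap(v, 2.55)), mean(v), tolerance = 1e-10)
  ## delta input reproduces the discrete Gaussian away from boundaries
  delta <- rep(0, 101); delta[51] <- 1
  sm <- smoothMap(delta, 3)
  r <- ceiling(4 * 3)
  kern <- exp(-(-r:r)^2 / (2 * 9)); kern <- kern / sum(kern)
  expect_equal(sm[(51 - r):(51 + r)], kern, tolerance = 1e-12)
})

test_that("null-run Z statistics are standard normal at moderate scale", {
  set.seed(37)
  nf <- 100L
  d <- taskDesign(data.frame(condition = "m", onset = c(20, 120),
                             duration = 15.4), runLength = 220)
  X <- buildDesignMatrix(d, 2.2, nf)
  Y <- matrix(rnorm(nf * 2000), nf)
  z <- activationZ(fitGLM(t(Y), X))
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.05)
})
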