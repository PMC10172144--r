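test_that("axis projection picks the nearest point with the low-index tie rule", {
  ax <- cbind(x = 0:9, y = 0)
  ## coincident vertex
  expect_equal(projectToAxis(cbind(7, 0), ax), 7L)
  ## exactly equidistant between positions 3 and 4 -> lower index
  expect_equal(projectToAxis(cbind(3.5, 2), ax), 3L)
  ## random vertices match the exhaustive scan
  set.seed(19)
  pts <- cbind(runif(40, -1, 10), runif(40, -3, 3))
  want <- apply(pts, 1, function(p)
    which.min(sqrt((ax[, 1] - p[1])^2 + (ax[, 2] - p[2])^2)) - 1L)
  expect_equal(projectToAxis(pts, ax), as.integer(want))
  expect_error(projectToAxis(pts, ax[0, , drop = FALSE]), "empty axis")
})

test_that("winner-take-all assigns the argmax with ties flagged", {
  z <- rbind(v1 = c(toe = 2, hand = 3), v2 = c(toe = 1, hand = 1))
  wta <- winnerTakeAll(z)
  expect_equal(wtaWinner(wta), c("hand", "toe"))
  expect_equal(unname(wta@tie), c(FALSE, TRUE))
  expect_error(winnerTakeAll(z[, 1, drop = FALSE]), "at least 2")
  ## top-percent display mask keeps the strongest vertices only
  set.seed(8)
  z2 <- cbind(a = rnorm(200), b = rnorm(200))
  wta2 <- winnerTakeAll(z2, topPercent = 10)
  expect_equal(sum(wtaDisplayMask(wta2)), 20L)
})

test_that("winner bands follow the injected peak ordering", {
  x <- 0:119
  z <- cbind(toes = gaussProfile(c(5, 10, 6), x),
             hand = gaussProfile(c(5, 50, 6), x),
             tongue = gaussProfile(c(5, 90, 6), x))
  wta <- winnerTakeAll(z)
  cent <- vapply(colnames(z), function(m) mean(x[wtaWinner(wta) == m]),
                 numeric(1))
  expect_true(all(diff(cent[c("toes", "hand", "tongue")]) > 0))
})

test_that("peak fitting recovers noiseless truths and orders two-peak fits", {
  x <- 0:59
  ## single peak, machine recovery, SSE ~ 0
  y1 <- gaussProfile(c(3, 30, 5), x)
  f <- fitPeakModels(data.frame(position = x, activation = y1,
                                inMask = TRUE))
  expect_lt(abs(f$onePeak@params[["b1"]] - 30), 1e-6)
  expect_lt(abs(f$onePeak@params[["a1"]] - 3), 1e-6)
  expect_lt(f$onePeak@sse, 1e-10)
  ## two peaks: the richer model is required
  y2 <- gaussProfile(c(3, 25, 5, 2, 45, 5), x)
  f2 <- fitPeakModels(data.frame(position = x, activation = y2,
                                 inMask = TRUE))
  expect_lt(f2$twoPeaks@sse, 1e-8)
  expect_gt(f2$onePeak@sse, 1)
  ## canonical ordering of the centres
  expect_lte(f2$twoPeaks@params[["b1"]], f2$twoPeaks@params[["b2"]])
  ## nestedness: two peaks never fit worse
  set.seed(44)
  for (i in 1:5) {
    y <- gaussProfile(c(3, 30, 8), x) + rnorm(60, 0, 1)
    ff <- fitPeakModels(data.frame(position = x, activation = y,
                                   inMask = TRUE))
    expect_lte(ff$twoPeaks@sse, ff$onePeak@sse + 1e-9)
  }
  ## all-zero profile collapses to the amplitude boundary
  f0 <- fitPeakModels(data.frame(position = x, activation = 0 * x,
                                 inMask = TRUE))
  expect_lt(f0$onePeak@sse, 1e-20)
  expect_lt(f0$onePeak@params[["a1"]], 1e-8)
})

test_that("the F comparison follows the printed formula", {
  mk <- function(n, sse, df) {
    pars <- if (n == 1) c(a1 = 1, b1 = 10, c1 = 5) else
      c(a1 = 1, b1 = 10, c1 = 5, a2 = 1, b2 = 20, c2 = 5)
    new("PeakFit", nPeaks = as.integer(n), params = pars, sse = sse,
        df = df, converged = TRUE, collapsed = FALSE)
  }
  cmp <- compareModelsF(mk(1, 10, 97), mk(2, 5, 94))
  expect_equal(cmp@fStat, (5 / 3) / (5 / 94), tolerance = 1e-12)
  expect_equal(cmp@pValue, pf((5 / 3) / (5 / 94), 3, 94,
                              lower.tail = FALSE), tolerance = 1e-12)
  ## equal SSE -> F = 0, p = 1
  cmp0 <- compareModelsF(mk(1, 5, 97), mk(2, 5, 94))
  expect_equal(cmp0@fStat, 0)
  expect_equal(cmp0@pValue, 1)
  ## perfect two-peak fit convention
  cmpInf <- compareModelsF(mk(1, 5, 97), mk(2, 0, 94))
  expect_equal(cmpInf@fStat, Inf)
  expect_equal(cmpInf@pValue, 0)
  expect_match(cmpInf@flag, "perfect")
  ## invariant to which peak is listed first in the fitted parameters
  x <- 0:59
  y <- gaussProfile(c(2, 45, 5, 3, 20, 5), x)
  ff <- fitPeakModels(data.frame(position = x, activation = y,
                                 inMask = TRUE))
  expect_lte(ff$twoPeaks@params[["b1"]], ff$twoPeaks@params[["b2"]])
})

test_that("movement selectivity is the margin over the runner-up", {
  z <- rbind(c(4, 1, 1, 1, 1, 1), c(2, 2, 2, 2, 2, 2))
  expect_equal(unname(movementSelectivity(z)), c(3, 0))
  expect_error(movementSelectivity(z[, 1, drop = FALSE]), "at least 2")
  ## broadly tuned inter-effector vertices score lower than effector centres
  x <- 0:119
  sharp <- cbind(toes = gaussProfile(c(6, 10, 4), x),
                 hand = gaussProfile(c(6, 50, 4), x),
                 tongue = gaussProfile(c(6, 90, 4), x),
                 abdominal = gaussProfile(c(1.5, 30, 8), x),
                 eyelid = gaussProfile(c(1.5, 70, 8), x),
                 swallowing = gaussProfile(c(1.5, 110, 8), x))
  sel <- movementSelectivity(sharp)
  lab <- rep(motorRegions(), each = 20)
  expect_lt(mean(sel[lab %in% interRegions()]),
            mean(sel[lab %in% effectorRegions()]))
})

test_that("coactivation profiles correlate region activation signatures", {
  z <- cbind(m1 = c(1, 1, 0, 0), m2 = c(2, 2, 0, 0), m3 = c(3, 3, 1, 1))
  lab <- c("inter_superior", "inter_middle", "foot", "foot")
  out <- coactivationProfiles(z, lab)
  ## identical profiles -> r = 1
  expect_equal(out$correlation["inter_superior", "inter_middle"], 1)
  ## region means equal brute-force averaging
  expect_equal(unname(out$profiles["foot", ]), c(0, 0, 1))
  ## anti-correlated profiles -> r = -1
  z2 <- cbind(m1 = c(1, 0), m2 = c(0, 1), m3 = c(-1, 2))
  out2 <- coactivationProfiles(z2, c("foot", "hand"))
  expect_equal(out2$correlation["foot", "hand"], -1)
  ## constant profile is masked
  z3 <- cbind(m1 = c(1, 1), m2 = c(1, 2), m3 = c(1, 3))
  out3 <- coactivationProfiles(z3, c("foot", "hand"))
  expect_true(is.na(out3$correlation["foot", "hand"]))
  expect_error(coactivationProfiles(z, lab, exclude = c("m1", "m2")),
               "at least 3")
})

test_that("LOWESS profile reproduces lines and finds noisy peaks", {
  x <- 0:49
  y <- 2 + 0.5 * x
  sm <- lowessProfile(x, y, span = 0.5)
  expect_equal(sm$smoothed, y, tolerance = 1e-8)
  ## flat data with full span stays constant
  smFlat <- lowessProfile(x, rep(1, 50), span = 1)
  expect_equal(smFlat$smoothed, rep(1, 50), tolerance = 1e-12)
  ## noisy two-peak data: smoothed maxima near the truth
  set.seed(55)
  x2 <- 0:119
  y2 <- gaussProfile(c(4, 30, 8, 4, 80, 8), x2) + rnorm(120, 0, 0.5)
  sm2 <- lowessProfile(x2, y2, span = 0.2)
  leftPeak <- sm2$position[which.max(sm2$smoothed[sm2$position < 55])]
  rightHalf <- sm2[sm2$position >= 55, ]
  rightPeak <- rightHalf$position[which.max(rightHalf$smoothed)]
  expect_lt(abs(leftPeak - 30), 2.5)
  expect_lt(abs(rightPeak - 80), 2.5)
  expect_error(lowessProfile(x, y, span = 0), "span")
  expect_error(lowessProfile(1:4, 1:4, span = 0.2), "at least 3")
})
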