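## Calibration suite: simulation studies that measure the statistical
## operating characteristics of the estimators on data from the synthetic
## generator. These back the package's stated guarantees (type-I control,
## power, lag recovery accuracy) and are what the acceptance script reruns.

#' Null calibration of the one- versus two-peak F-test
#'
#' Simulates activation profiles from a one-peak truth plus white noise,
#' fits both peak models and applies the nested F-test, and reports the
#' empirical two-peak rejection rate at `alpha` and the Kolmogorov-Smirnov
#' p-value for uniformity of the F-test p-values.
#'
#' @param nProfiles number of simulated profiles.
#' @param nPositions profile length (axis positions 0..nPositions-1).
#' @param truth one-peak truth parameters c(a1, b1, c1).
#' @param noiseRatio noise sd as a fraction of the true amplitude.
#' @param alpha nominal level.
#' @param minWidth minimum peak width passed to the fitter.
#' @param seed RNG seed.
#' @return list with pValues, rejectionRate, ksP.
#' @export
calibratePeakFTest <- function(nProfiles = 500L, nPositions = 60L,
                               truth = c(a1 = 3, b1 = 30, c1 = 8),
                               noiseRatio = 0.5, alpha = 0.05,
                               minWidth = 4, seed = 1L) {
  set.seed(deriveSeed(seed, 401L))
  x <- seq_len(nPositions) - 1
  signal <- gaussPeaks(truth, x)
  noiseSd <- noiseRatio * truth[[1L]]
  pv <- vapply(seq_len(nProfiles), function(i) {
    y <- signal + rnorm(nPositions, 0, noiseSd)
    fits <- fitPeakModels(data.frame(position = x, activation = y,
                                     inMask = TRUE), minWidth = minWidth)
    compareModelsF(fits$onePeak, fits$twoPeaks, alpha = alpha)@pValue
  }, numeric(1))
  list(pValues = pv, rejectionRate = mean(pv < alpha),
       ksP = stats::ks.test(pv, "punif")$p.value)
}

#' Power and recovery of the two-peak model comparison
#'
#' Simulates profiles from a two-peak truth (well-separated peaks, strong
#' amplitude-to-noise ratio), and reports how often the two-peak model is
#' preferred at `pThreshold` and how accurately the peak centres are
#' recovered.
#'
#' @inheritParams calibratePeakFTest
#' @param truth two-peak truth parameters c(a1, b1, c1, a2, b2, c2).
#' @param noiseSd noise standard deviation (default: smaller amplitude / 3).
#' @param pThreshold preference threshold on the F-test p-value.
#' @return list with preferRate, centerErrors (per profile, worst of the
#'   two centres), medianCenterError.
#' @export
peakFTestPower <- function(nProfiles = 200L, nPositions = 60L,
                           truth = c(a1 = 3, b1 = 18, c1 = 5,
                                     a2 = 2.5, b2 = 42, c2 = 6),
                           noiseSd = min(truth[c(1L, 4L)]) / 3,
                           pThreshold = 0.001, minWidth = 4, seed = 1L) {
  set.seed(deriveSeed(seed, 402L))
  x <- seq_len(nPositions) - 1
  signal <- gaussPeaks(truth, x)
  bTrue <- sort(truth[c(2L, 5L)])
  prefer <- logical(nProfiles); err <- numeric(nProfiles)
  for (i in seq_len(nProfiles)) {
    y <- signal + rnorm(nPositions, 0, noiseSd)
    fits <- fitPeakModels(data.frame(position = x, activation = y,
                                     inMask = TRUE), minWidth = minWidth)
    cmp <- compareModelsF(fits$onePeak, fits$twoPeaks)
    prefer[i] <- cmp@pValue < pThreshold
    bHat <- sort(fits$twoPeaks@params[c("b1", "b2")])
    err[i] <- max(abs(bHat - bTrue))
  }
  list(preferRate = mean(prefer), centerErrors = err,
       medianCenterError = stats::median(err))
}

#' Lag recovery accuracy of the TD-matrix estimator
#'
#' Injects band-limited fractional time shifts into generated resting runs
#' (one vertex per region, all regions driven by a single shared infra-slow
#' latent, white noise at the requested SNR) and measures the absolute
#' error of the recovered pairwise delays, together with the worst
#' antisymmetry violation on the valid mask.
#'
#' @param nSeeds number of simulated runs.
#' @param shifts injected delays in seconds, one per probed region pair.
#' @param tr repetition time (seconds).
#' @param nFrames frames per run.
#' @param snr ratio of signal variance to noise variance.
#' @param maxLag CCF window half-width in frames.
#' @param seed RNG seed.
#' @return list with errors (matrix nSeeds x shifts), medianAbsError,
#'   antisymmetryMax, validRate.
#' @export
lagRecoveryError <- function(nSeeds = 100L, shifts = c(0.5, 1.0, 1.5),
                             tr = 1.1, nFrames = 800L, snr = 2,
                             maxLag = 8L, seed = 1L) {
  stopifnot(length(shifts) == 3L)
  strip <- generateStrip(setNames(rep(1L, 6L), motorRegions()),
                         offAxis = c(CON = 0L))
  regs <- levels(regionLabels(strip))
  delays <- setNames(rep(0, length(regs)), regs)
  delays[c("inter_superior", "hand", "inter_middle")] <- shifts
  truth <- syntheticTruth(
    strip,
    networkAssignments = setNames(rep("net", length(regs)), regs),
    globalWeight = 0, delays = delays, noiseSd = sqrt(1 / snr),
    seed = seed)
  errs <- matrix(NA_real_, nSeeds, 3L,
                 dimnames = list(NULL, paste0("shift_", shifts)))
  antisym <- 0; nValid <- 0L; nPairs <- 0L
  for (i in seq_len(nSeeds)) {
    run <- generateRestRun(strip, truth, nFrames = nFrames, tr = tr,
                           seed = deriveSeed(seed, 500L + i))
    tdm <- tdMatrix(run, maxLag = maxLag, tr = tr)
    td <- tdValues(tdm); v <- tdValid(tdm)
    lab <- as.character(regionLabels(strip))
    ref <- which(lab == "foot")
    probes <- match(c("inter_superior", "hand", "inter_middle"), lab)
    for (k in 1:3) {
      if (v[probes[k], ref])
        errs[i, k] <- abs(td[probes[k], ref] - shifts[k])
    }
    off <- v & t(v); diag(off) <- FALSE
    if (any(off)) antisym <- max(antisym, max(abs(td[off] + t(td)[off])))
    nValid <- nValid + sum(v[upper.tri(v)])
    nPairs <- nPairs + sum(upper.tri(v))
  }
  list(errors = errs,
       medianAbsError = stats::median(errs, na.rm = TRUE),
       antisymmetryMax = antisym, validRate = nValid / nPairs)
}

#' Null calibration of the GLM Z-scores
#'
#' Fits the block GLM to pure-noise runs and summarizes the run-level and
#' second-level Z distributions, which should be standard normal under the
#' null.
#'
#' @param nVertices number of simulated vertices.
#' @param nFrames frames per run.
#' @param nRuns runs entering the second level.
#' @param tr repetition time (seconds).
#' @param seed RNG seed.
#' @return list with runZ (vector), runZMean, runZSd, secondZ (vector),
#'   secondZMean, secondZSd.
#' @export
glmNullCalibration <- function(nVertices = 10000L, nFrames = 120L,
                               nRuns = 8L, tr = 2.2, seed = 1L) {
  set.seed(deriveSeed(seed, 601L))
  d <- taskDesign(data.frame(condition = c("a", "a", "b", "b"),
                             onset = c(11, 110, 44, 176),
                             duration = 15.4),
                  runLength = nFrames * tr)
  X <- buildDesignMatrix(d, tr, nFrames)
  maps <- lapply(seq_len(nRuns), function(r)
    fitGLM(matrix(rnorm(nVertices * nFrames), nVertices), X))
  runZ <- as.numeric(activationZ(maps[[1L]]))
  subj <- secondLevel(maps)
  secondZ <- as.numeric(activationZ(subj))
  list(runZ = runZ, runZMean = mean(runZ), runZSd = sd(runZ),
       secondZ = secondZ, secondZMean = mean(secondZ),
       secondZSd = sd(secondZ))
}

#' Type-I error of the paired t-test and BH family control
#'
#' Simulates null paired samples and reports the empirical rejection rate
#' of the two-tailed paired t-test at `alpha` (vectorized across
#' replicates; a subset is cross-checked against `pairedTTestFDR()` in the
#' test suite), plus the proportion of all-null families of `familySize`
#' comparisons in which Benjamini-Hochberg makes any discovery (equal to
#' alpha for independent tests).
#'
#' @param nReps number of null replicates.
#' @param nSubjects paired sample size.
#' @param alpha nominal level.
#' @param familySize comparisons per BH family.
#' @param nFamilies number of simulated families.
#' @param seed RNG seed.
#' @return list with rejectionRate, pValues, familyDiscoveryRate.
#' @export
pairedTTestTypeI <- function(nReps = 10000L, nSubjects = 7L, alpha = 0.05,
                             familySize = 3L, nFamilies = 1000L,
                             seed = 1L) {
  set.seed(deriveSeed(seed, 701L))
  d <- matrix(rnorm(nSubjects * nReps), nSubjects) -
    matrix(rnorm(nSubjects * nReps), nSubjects)
  mu <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2L, mu)^2) / (nSubjects - 1L))
  tt <- mu / (s / sqrt(nSubjects))
  pv <- 2 * pt(abs(tt), nSubjects - 1L, lower.tail = FALSE)
  ## BH families under the global null
  fam <- matrix(pv[seq_len(familySize * nFamilies)], familySize)
  anyDisc <- apply(fam, 2L, function(p)
    any(p.adjust(p, "BH") < alpha))
  list(rejectionRate = mean(pv < alpha), pValues = pv,
       familyDiscoveryRate = mean(anyDisc))
}
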