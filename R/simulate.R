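## Synthetic BOLD generation: infra-slow latent signals, band-limited lag
## injection, haemodynamic task responses, and structural scalar maps.

## An infra-slow latent signal: random Fourier coefficients at frequencies
## strictly below `cutoff`, conjugate-symmetrized and inverted, then scaled
## to unit sd. Being strictly band-limited and periodic, these signals can
## be delayed by arbitrary fractional amounts exactly via phase rotation.
infraSlowLatent <- function(nFrames, tr, cutoff = 0.1) {
  freqs <- (seq_len(nFrames) - 1L) / (nFrames * tr)
  k <- which(freqs > 0 & freqs < cutoff & (seq_len(nFrames) - 1L) <= nFrames / 2)
  if (!length(k))
    stop("run too short to contain any infra-slow frequency component")
  spec <- complex(real = rep(0, nFrames))
  spec[k] <- complex(real = rnorm(length(k)), imaginary = rnorm(length(k)))
  spec[nFrames - k + 2L] <- Conj(spec[k])
  s <- Re(fft(spec, inverse = TRUE))
  s / sqrt(mean((s - mean(s))^2))
}

## Exact fractional delay of a periodic band-limited signal by frequency-
## domain phase rotation: y(t) = x(t - delaySeconds).
bandShift <- function(x, delaySeconds, tr) {
  if (delaySeconds == 0) return(x)
  n <- length(x)
  fr <- (seq_len(n) - 1L) / (n * tr)
  nyq <- 1 / (2 * tr)
  fr[fr > nyq] <- fr[fr > nyq] - 1 / tr
  Re(fft(fft(x) * exp(-2i * pi * fr * delaySeconds), inverse = TRUE) / n)
}

#' Generate a synthetic resting-state run
#'
#' Every vertex time course is the infra-slow (< 0.1 Hz) signal of its
#' region -- a weighted mixture of band-limited latent signals, delayed by
#' the region's injected lag via frequency-domain phase shift -- plus white
#' noise at the truth's `noiseSd`. Regions sharing a network latent are
#' mutually correlated; all regions share a weak global latent.
#'
#' @param strip a \linkS4class{CorticalStrip}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nFrames number of frames (>= 64).
#' @param tr repetition time in seconds.
#' @param seed integer seed; identical seeds give identical runs.
#' @return A \linkS4class{BoldRun} with `runType = "rest"`.
#' @examples
#' strip <- generateStrip(10, offAxis = c(CON = 10))
#' truth <- syntheticTruth(strip, noiseSd = 0.2, seed = 3)
#' run <- generateRestRun(strip, truth, nFrames = 128, tr = 1.1, seed = 3)
#' dim(run)
#' @export
generateRestRun <- function(strip, truth, nFrames = 800L, tr = 1.1,
                            seed = truth@seed) {
  if (nFrames < 64L) stop("a resting run needs at least 64 frames")
  .assertScalar(tr, "tr")
  maxLag <- max(abs(pairwiseLags(truth)))
  if (maxLag >= tr * nFrames / 4)
    stop("injected lags exceed a quarter of the run duration")

  set.seed(deriveSeed(seed, 101L))
  loadings <- truth@loadings
  latents <- vapply(colnames(loadings), function(k)
    infraSlowLatent(nFrames, tr), numeric(nFrames))

  regions <- rownames(loadings)
  regionSignal <- matrix(0, length(regions), nFrames,
                         dimnames = list(regions, NULL))
  for (r in regions) {
    s <- rep(0, nFrames)
    for (k in colnames(loadings)) {
      wk <- loadings[r, k]
      if (wk != 0) s <- s + wk * bandShift(latents[, k], truth@delays[[r]], tr)
    }
    regionSignal[r, ] <- s
  }

  lab <- as.character(regionLabels(strip))
  data <- regionSignal[lab, , drop = FALSE]
  if (truth@noiseSd > 0)
    data <- data + matrix(rnorm(length(data), 0, truth@noiseSd), nrow(data))
  dimnames(data) <- list(rownames(coords(strip)),
                         paste0("f", seq_len(nFrames)))
  .newBoldRun(data, tr, "rest", strip)
}

.newBoldRun <- function(data, tr, runType, strip = NULL) {
  rd <- if (!is.null(strip)) {
    S4Vectors::DataFrame(region = as.character(regionLabels(strip)),
                         axisPos = axisPositions(strip),
                         x = coords(strip)[, 1L], y = coords(strip)[, 2L])
  } else S4Vectors::DataFrame(matrix(nrow = nrow(data), ncol = 0L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bold = data), rowData = rd,
    metadata = list(tr = tr, runType = runType))
  new("BoldRun", se)
}

#' @rdname generateRestRun
#' @param run a BoldRun.
#' @export
tr <- function(run) S4Vectors::metadata(run)$tr

#' @rdname generateRestRun
#' @export
runType <- function(run) S4Vectors::metadata(run)$runType

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with modes at `peak` (6 s) and
#' `undershoot` (16 s) and undershoot ratio 1/6, scaled so the maximum of
#' the continuous response is 1.
#'
#' @param t time in seconds (vectorized).
#' @param peak,undershoot,ratio shape of the response.
#' @return numeric vector of HRF values.
#' @export
doubleGammaHRF <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  g <- function(t, mode) {
    shape <- mode + 1          # rate 1: gamma density mode = shape - 1
    out <- rep(0, length(t))
    pos <- t > 0
    out[pos] <- exp((shape - 1) * log(t[pos]) - t[pos] - lgamma(shape))
    out
  }
  h <- function(t) g(t, peak) - ratio * g(t, undershoot)
  fine <- h(seq(0, 40, by = 0.01))
  h(t) / max(fine)
}

#' Task designs
#'
#' `taskDesign()` builds a validated \linkS4class{TaskDesign} from an event
#' table. `blockBattery()` builds the standard movement-battery block run:
#' each block is a 2.2 s cue followed by 12 paced movements at 1.1 s
#' spacing (block duration 15.4 s); blocks of each condition alternate in a
#' fixed round-robin order with interspersed rest blocks.
#' `planningExecutionDesign()` builds an event-related run with point
#' (duration-0) planning and execution events per trial.
#'
#' @param events data.frame with columns condition, onset, duration and
#'   optionally phase.
#' @param runLength run duration in seconds.
#' @return A \linkS4class{TaskDesign}.
#' @export
taskDesign <- function(events, runLength) {
  if (is.null(events$phase))
    events$phase <- rep(NA_character_, nrow(events))
  events <- events[, c("condition", "onset", "duration", "phase")]
  new("TaskDesign", events = events, runLength = runLength)
}

#' @rdname taskDesign
#' @param conditions condition labels.
#' @param blocksPerCondition blocks of each condition per run.
#' @param restBlocks rest blocks appended between condition cycles.
#' @param cue,movementsPerBlock,spacing block timing in seconds; the block
#'   duration is `cue + movementsPerBlock * spacing`.
#' @param tailRest seconds of rest appended after the final block.
#' @export
blockBattery <- function(conditions, blocksPerCondition = 2L,
                         restBlocks = 3L, cue = 2.2,
                         movementsPerBlock = 12L, spacing = 1.1,
                         tailRest = 15.4) {
  blockDur <- cue + movementsPerBlock * spacing
  order <- rep(conditions, blocksPerCondition)
  ## spread rest blocks evenly through the sequence (marked NA, unmodelled)
  if (restBlocks > 0L) {
    at <- round(seq(1, length(order) + 1L, length.out = restBlocks))
    for (i in seq_along(at))
      order <- append(order, NA_character_, after = at[i] + i - 2L)
  }
  onsets <- (seq_along(order) - 1L) * blockDur
  keep <- !is.na(order)
  taskDesign(data.frame(condition = order[keep], onset = onsets[keep],
                        duration = blockDur, phase = NA_character_),
             runLength = length(order) * blockDur + tailRest)
}

#' @rdname taskDesign
#' @param nTrials number of planning/execution trials.
#' @param planDur seconds from planning cue to execution cue.
#' @param trialSpacing seconds between consecutive trial onsets.
#' @export
planningExecutionDesign <- function(nTrials = 12L, planDur = 4.4,
                                    trialSpacing = 17.6) {
  onsets <- (seq_len(nTrials) - 1L) * trialSpacing
  ev <- rbind(
    data.frame(condition = "planning", onset = onsets, duration = 0,
               phase = "planning"),
    data.frame(condition = "execution", onset = onsets + planDur,
               duration = 0, phase = "execution"))
  taskDesign(ev[order(ev$onset), ], runLength = nTrials * trialSpacing + 17.6)
}

#' Generate a synthetic task run
#'
#' The response amplitude of vertex v to condition m is the true spatial
#' profile `a1*exp(-((x - b1)/c1)^2) (+ second peak)` evaluated at v's axis
#' position (for motor-strip vertices), plus any region-level amplitude from
#' `regionTaskAmplitudes` (e.g. broad inter-effector coactivation or CON
#' task engagement). The time course is amplitude x (boxcar or event train
#' convolved with the double-gamma HRF) plus white noise.
#'
#' @inheritParams generateRestRun
#' @param design a \linkS4class{TaskDesign}.
#' @param tr repetition time in seconds.
#' @return A \linkS4class{BoldRun} with the design's regressor matrix in
#'   `metadata(run)$design`.
#' @export
generateTaskRun <- function(strip, truth, design, tr = 2.2,
                            seed = truth@seed) {
  stopifnot(is(design, "TaskDesign"))
  nFrames <- floor(design@runLength / tr)
  if (nFrames < 2L) stop("design run length too short for this tr")
  X <- buildDesignMatrix(design, tr, nFrames, intercept = FALSE)
  conds <- colnames(X)

  amp <- matrix(0, length(strip), length(conds),
                dimnames = list(rownames(coords(strip)), conds))
  pos <- axisPositions(strip)
  onStrip <- as.character(regionLabels(strip)) %in% .motorRegions
  for (m in conds) {
    p <- truth@peakParams[[m]]
    if (!is.null(p))
      amp[onStrip, m] <- gaussPeaks(p, pos[onStrip])
    rta <- truth@regionTaskAmplitudes
    if (length(rta) && m %in% colnames(rta)) {
      for (r in intersect(rownames(rta), levels(regionLabels(strip)))) {
        if (rta[r, m] != 0)
          amp[as.character(regionLabels(strip)) == r, m] <-
            amp[as.character(regionLabels(strip)) == r, m] + rta[r, m]
      }
    }
  }

  data <- amp %*% t(X)
  set.seed(deriveSeed(seed, 211L))
  if (truth@noiseSd > 0)
    data <- data + matrix(rnorm(length(data), 0, truth@noiseSd), nrow(data))
  dimnames(data) <- list(rownames(coords(strip)), paste0("f", seq_len(nFrames)))
  run <- .newBoldRun(data, tr, if (any(design@events$duration > 0))
    "block_task" else "event_task", strip)
  S4Vectors::metadata(run)$design <- design
  run
}

## Evaluate a 1- or 2-peak Gaussian profile parameter vector at positions x.
gaussPeaks <- function(p, x) {
  out <- p[1L] * exp(-((x - p[2L]) / p[3L])^2)
  if (length(p) == 6L)
    out <- out + p[4L] * exp(-((x - p[5L]) / p[6L])^2)
  out[is.na(x)] <- 0
  out
}

#' Generate synthetic structural scalar maps
#'
#' Per-vertex draws of cortical thickness (mm), sub-cortical fractional
#' anisotropy and intracortical myelin density from region-wise normal
#' distributions. Myelin is additionally returned normalized by its mean
#' over the precentral-gyrus (motor strip) vertices, so the normalized map
#' has mean exactly 1 there.
#'
#' @param strip a \linkS4class{CorticalStrip}.
#' @param regionEffects data.frame with columns region, metric
#'   (thickness/fa/myelin), mean, sd. See `defaultStructuralEffects()`.
#' @param seed integer seed.
#' @return data.frame with columns vertex, region, thickness, fa, myelin,
#'   myelinNorm.
#' @export
generateStructuralMaps <- function(strip,
                                   regionEffects = defaultStructuralEffects(),
                                   seed = 1L) {
  if (any(regionEffects$sd < 0)) stop("negative sd in regionEffects")
  set.seed(deriveSeed(seed, 307L))
  lab <- as.character(regionLabels(strip))
  out <- data.frame(vertex = rownames(coords(strip)), region = lab)
  for (metric in c("thickness", "fa", "myelin")) {
    v <- rep(NA_real_, length(lab))
    for (r in unique(lab)) {
      row <- regionEffects[regionEffects$region == r &
                             regionEffects$metric == metric, ]
      if (!nrow(row)) next
      idx <- lab == r
      v[idx] <- rnorm(sum(idx), row$mean[1L], row$sd[1L])
    }
    out[[metric]] <- v
  }
  if (any(out$thickness <= 0, na.rm = TRUE))
    stop("drawn thickness values must stay positive; check regionEffects")
  pg <- lab %in% .motorRegions
  out$myelinNorm <- out$myelin / mean(out$myelin[pg])
  out
}

#' @rdname generateStructuralMaps
#' @export
defaultStructuralEffects <- function() {
  regs <- c(.motorRegions, .offAxisRegions)
  isInter <- regs %in% .interRegions
  rbind(
    data.frame(region = regs, metric = "thickness",
               mean = ifelse(isInter, 2.3, 2.7), sd = 0.15),
    data.frame(region = regs, metric = "fa",
               mean = ifelse(isInter, 0.45, 0.40), sd = 0.03),
    data.frame(region = regs, metric = "myelin",
               mean = ifelse(regs == "hand", 1.25,
                             ifelse(isInter, 1.10, 0.95)), sd = 0.08))
}
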