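#' @import methods
#' @importFrom stats approx coef convolve cor fft lowess mvfft na.omit
#'   p.adjust pf pnorm pt qnorm quantile rnorm sd setNames t.test var
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata DataFrame
NULL

## Canonical region vocabulary. The six motor-strip regions are laid out
## along the dorsal -> ventral axis in interdigitated order; the remaining
## labels are off-strip territories used for connectivity targets.
.motorRegions <- c("foot", "inter_superior", "hand", "inter_middle",
                   "mouth", "inter_inferior")
.interRegions <- c("inter_superior", "inter_middle", "inter_inferior")
.effectorRegions <- c("foot", "hand", "mouth")
.offAxisRegions <- c("CON", "S1_adjacent", "background")
.allRegions <- c(.motorRegions, .offAxisRegions)

#' Region vocabulary
#'
#' Region labels used throughout the package. `motorRegions()` returns the
#' six precentral-strip regions in dorsal-to-ventral interdigitated order
#' (foot, superior inter-effector, hand, middle inter-effector, mouth,
#' inferior inter-effector); `interRegions()` and `effectorRegions()` the
#' corresponding subsets.
#'
#' @return Character vector of region labels.
#' @export
motorRegions <- function() .motorRegions

#' @rdname motorRegions
#' @export
interRegions <- function() .interRegions

#' @rdname motorRegions
#' @export
effectorRegions <- function() .effectorRegions

#' CorticalStrip: synthetic cortical-sheet geometry
#'
#' A 1-D cortical strip standing in for the precentral gyrus: vertex
#' coordinates in mm-like units, an ordered dorsal-to-ventral axis line of
#' vertex indices, and a region label per vertex.
#'
#' @slot coords numeric matrix (vertices x 2) of positions.
#' @slot axisLine integer vector of vertex indices forming the ordered
#'   dorsal -> ventral seed line.
#' @slot regionLabels factor of per-vertex region labels.
#' @slot hemisphere single character tag ("L" or "R").
#' @export
setClass("CorticalStrip",
  representation(coords = "matrix", axisLine = "integer",
                 regionLabels = "factor", hemisphere = "character"))

setValidity("CorticalStrip", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (length(object@regionLabels) != n)
    msg <- c(msg, "one region label per vertex required")
  if (anyDuplicated(object@axisLine))
    msg <- c(msg, "axisLine indices must be unique")
  if (length(object@axisLine) &&
      (min(object@axisLine) < 1L || max(object@axisLine) > n))
    msg <- c(msg, "axisLine indices out of range")
  if (!all(levels(object@regionLabels) %in% .allRegions))
    msg <- c(msg, "unknown region label")
  ## interdigitated ordering along the axis (only for regions present)
  axLab <- as.character(object@regionLabels[object@axisLine])
  firstSeen <- unique(axLab)
  expected <- .motorRegions[.motorRegions %in% firstSeen]
  if (!identical(firstSeen[firstSeen %in% .motorRegions], expected))
    msg <- c(msg, "axis regions not in interdigitated dorsal->ventral order")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth for the synthetic generator
#'
#' Holds the latent-signal loadings (region x latent weight matrix), the
#' per-region temporal delays in seconds (pairwise lags are the antisymmetric
#' differences of these), true spatial activation peak parameters per
#' movement, optional region-level task amplitudes, and the noise scale.
#'
#' @slot loadings numeric matrix (region x latent signal) of mixing weights.
#' @slot delays named numeric, per-region signal delay in seconds; the
#'   injected pairwise lag between regions i and j is `delays[i] - delays[j]`
#'   (positive means i's signal occurs later).
#' @slot peakParams named list; per movement a numeric vector
#'   `c(a1, b1, c1)` or `c(a1, b1, c1, a2, b2, c2)` describing the true
#'   spatial activation profile along the axis.
#' @slot regionTaskAmplitudes numeric matrix (region x condition) of
#'   additional region-level response amplitudes (e.g. broad inter-effector
#'   coactivation), or a 0 x 0 matrix.
#' @slot noiseSd single non-negative numeric, white-noise sd per vertex.
#' @slot seed integer root seed.
#' @export
setClass("SyntheticTruth",
  representation(loadings = "matrix", delays = "numeric",
                 peakParams = "list", regionTaskAmplitudes = "matrix",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (is.null(rownames(object@loadings)) || is.null(colnames(object@loadings)))
    msg <- c(msg, "loadings must have region rownames and latent colnames")
  if (!all(names(object@delays) %in% rownames(object@loadings)))
    msg <- c(msg, "delays must be named by regions present in loadings")
  for (p in object@peakParams) {
    if (!length(p) %in% c(3L, 6L)) {
      msg <- c(msg, "peakParams entries must have 3 or 6 values"); break
    }
    a <- p[seq(1L, length(p), by = 3L)]; cc <- p[seq(3L, length(p), by = 3L)]
    if (any(a < 0)) { msg <- c(msg, "peak amplitudes must be >= 0"); break }
    if (any(cc <= 0)) { msg <- c(msg, "peak widths must be > 0"); break }
  }
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' BoldRun: a vertex x frame BOLD matrix
#'
#' Thin \linkS4class{SummarizedExperiment} subclass: the single assay
#' `"bold"` holds the vertex x frame matrix, `rowData` carries vertex
#' metadata (region label, axis position) when constructed from a
#' \linkS4class{CorticalStrip}, and `metadata` records the repetition time
#' `tr` (seconds) and the `runType` ("rest", "block_task" or "event_task").
#'
#' @export
setClass("BoldRun", contains = "SummarizedExperiment")

setValidity("BoldRun", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (is.null(md$tr) || length(md$tr) != 1L || !is.finite(md$tr) || md$tr <= 0)
    msg <- c(msg, "metadata tr must be a single positive number")
  if (!identical(md$runType %in% c("rest", "block_task", "event_task"), TRUE))
    msg <- c(msg, "metadata runType must be rest, block_task or event_task")
  if (ncol(object) < 2L) msg <- c(msg, "a run needs at least 2 frames")
  if (!"bold" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'bold' required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "bold"))))
    msg <- c(msg, "BOLD values must all be finite")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: Fisher-z vertex connectivity
#'
#' Symmetric vertex x vertex matrix of Fisher-transformed Pearson
#' correlations (r clipped to +/-(1 - 1e-7) before atanh) with a logical
#' validity mask. The diagonal is excluded (NA, mask FALSE), as are rows and
#' columns of zero-variance vertices.
#'
#' @slot z numeric matrix of Fisher-z values (NA where masked).
#' @slot mask logical matrix, TRUE for valid pairs.
#' @export
setClass("ConnectivityMatrix",
  representation(z = "matrix", mask = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@z), dim(object@mask)))
    msg <- c(msg, "z and mask dimensions differ")
  if (nrow(object@z) != ncol(object@z)) msg <- c(msg, "z must be square")
  zz <- object@z[object@mask]
  if (length(zz) && !all(is.finite(zz)))
    msg <- c(msg, "masked-in z values must be finite")
  if (any(diag(object@mask))) msg <- c(msg, "diagonal must be masked out")
  if (length(msg)) msg else TRUE
})

#' CCFProfile: a lagged cross-covariance function
#'
#' Normalized cross-covariance of two standardized time series over a
#' symmetric integer-frame lag window.
#'
#' @slot lags integer frame offsets, symmetric about 0.
#' @slot values normalized cross-covariance at each offset.
#' @slot tr repetition time in seconds.
#' @export
setClass("CCFProfile",
  representation(lags = "integer", values = "numeric", tr = "numeric"))

setValidity("CCFProfile", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@values))
    msg <- c(msg, "lags and values lengths differ")
  if (!identical(object@lags, -rev(object@lags)))
    msg <- c(msg, "lags must be symmetric about 0")
  if (length(msg)) msg else TRUE
})

#' TDMatrix: antisymmetric time-delay matrix
#'
#' Pairwise signal time delays in seconds, with `td[i, j] > 0` meaning the
#' signal of element i occurs later than that of element j; antisymmetric on
#' the valid mask, zero diagonal.
#'
#' @slot td numeric matrix of delays (seconds; NA where invalid).
#' @slot valid logical matrix of pair validity.
#' @export
setClass("TDMatrix", representation(td = "matrix", valid = "matrix"))

setValidity("TDMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@td), dim(object@valid)))
    msg <- c(msg, "td and valid dimensions differ")
  v <- object@valid & t(object@valid); diag(v) <- FALSE
  if (any(v) && max(abs(object@td[v] + t(object@td)[v])) > 0)
    msg <- c(msg, "td must be exactly antisymmetric on the valid mask")
  if (any(diag(object@td) != 0)) msg <- c(msg, "diagonal delays must be 0")
  if (length(msg)) msg else TRUE
})

#' ActivationMap: per-condition activation statistics
#'
#' Vertex x condition matrices of GLM betas, t statistics and signed
#' Z-scores, with the degrees of freedom and analysis level. Z values are
#' clamped to |Z| <= 8.2; second-level cells with zero between-run variance
#' and non-zero mean are flagged degenerate (Z set NA).
#'
#' @slot beta,tstat,z numeric matrices (vertex x condition).
#' @slot df single numeric, degrees of freedom of the t statistics.
#' @slot level "run" or "subject".
#' @slot degenerate logical matrix flagging zero-variance cells.
#' @export
setClass("ActivationMap",
  representation(beta = "matrix", tstat = "matrix", z = "matrix",
                 df = "numeric", level = "character",
                 degenerate = "matrix"))

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (!identical(dim(object@beta), dim(object@z)) ||
      !identical(dim(object@tstat), dim(object@z)))
    msg <- c(msg, "beta, tstat and z dimensions must agree")
  if (!object@level %in% c("run", "subject"))
    msg <- c(msg, "level must be 'run' or 'subject'")
  ok <- is.finite(object@z) & is.finite(object@tstat)
  if (any(sign(object@z[ok]) * sign(object@tstat[ok]) < 0))
    msg <- c(msg, "Z and t must agree in sign")
  if (length(msg)) msg else TRUE
})

#' TaskDesign: condition onsets and durations
#'
#' Event table for one task run: condition label, onset and duration in
#' seconds (duration 0 encodes a point event), and an optional phase tag
#' ("planning"/"execution") for event-related designs.
#'
#' @slot events data.frame with columns condition, onset, duration, phase.
#' @slot runLength run duration in seconds.
#' @export
setClass("TaskDesign",
  representation(events = "data.frame", runLength = "numeric"))

setValidity("TaskDesign", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("condition", "onset", "duration", "phase")
  if (!all(need %in% names(ev))) {
    return("events needs columns condition, onset, duration, phase")
  }
  if (any(ev$onset < 0)) msg <- c(msg, "onsets must be >= 0")
  if (any(ev$duration < 0)) msg <- c(msg, "durations must be >= 0")
  if (any(ev$onset + ev$duration > object@runLength + 1e-9))
    msg <- c(msg, "an event extends past the end of the run")
  if (length(msg)) msg else TRUE
})

#' PeakFit: a fitted one- or two-peak Gaussian activation profile
#'
#' Constrained least-squares fit of
#' `a1 * exp(-((x - b1)/c1)^2) (+ a2 * exp(-((x - b2)/c2)^2))`
#' to an axis activation profile. Amplitudes are constrained non-negative,
#' centres to the masked position range, widths to a configurable minimum.
#' For two peaks the parameters are stored with `b1 <= b2`.
#'
#' @slot nPeaks 1 or 2.
#' @slot params named numeric: a1, b1, c1 (and a2, b2, c2).
#' @slot sse residual sum of squared errors.
#' @slot df fitted points minus number of parameters.
#' @slot converged logical, at least one optimizer start converged.
#' @slot collapsed logical; TRUE for a two-peak fit whose centres ended
#'   within one axis unit of each other.
#' @export
setClass("PeakFit",
  representation(nPeaks = "integer", params = "numeric", sse = "numeric",
                 df = "numeric", converged = "logical",
                 collapsed = "logical"))

setValidity("PeakFit", function(object) {
  msg <- character()
  np <- object@nPeaks
  if (!np %in% c(1L, 2L)) msg <- c(msg, "nPeaks must be 1 or 2")
  if (length(object@params) != 3L * np)
    msg <- c(msg, "params length must be 3 * nPeaks")
  a <- object@params[seq(1L, length(object@params), by = 3L)]
  cc <- object@params[seq(3L, length(object@params), by = 3L)]
  if (any(a < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(cc <= 0)) msg <- c(msg, "widths must be > 0")
  if (object@sse < 0) msg <- c(msg, "sse must be >= 0")
  if (np == 2L && object@params[2L] > object@params[5L] + 1e-9)
    msg <- c(msg, "two-peak params must be ordered b1 <= b2")
  if (length(msg)) msg else TRUE
})

#' ModelComparison: nested F-test between peak models
#'
#' F = ((SSE1 - SSE2) / (df1 - df2)) / (SSE2 / df2) with upper-tail p from
#' the F distribution on (df1 - df2, df2) degrees of freedom.
#'
#' @slot fStat F statistic (Inf when SSE2 = 0).
#' @slot pValue upper-tail p value.
#' @slot dfNum,dfDen numerator and denominator degrees of freedom.
#' @slot preferred 1 or 2, the model preferred at the configured alpha.
#' @slot flag character annotation ("", "perfect_two_peak_fit",
#'   "collapsed_two_peak").
#' @export
setClass("ModelComparison",
  representation(fStat = "numeric", pValue = "numeric", dfNum = "numeric",
                 dfDen = "numeric", preferred = "integer",
                 flag = "character"))

setValidity("ModelComparison", function(object) {
  msg <- character()
  if (is.finite(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p value must lie in [0, 1]")
  if (!object@preferred %in% c(1L, 2L))
    msg <- c(msg, "preferred must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' WTAMap: winner-take-all movement assignment
#'
#' Per-vertex winning movement (argmax of Z across conditions), exact-tie
#' flag, selectivity (best minus second-best Z) and an optional top-percent
#' display mask.
#'
#' @slot winner character vector of winning condition labels.
#' @slot tie logical exact-tie flag.
#' @slot selectivity numeric best-minus-second-best Z.
#' @slot displayMask logical, TRUE for vertices surviving the display
#'   threshold.
#' @export
setClass("WTAMap",
  representation(winner = "character", tie = "logical",
                 selectivity = "numeric", displayMask = "logical"))

setValidity("WTAMap", function(object) {
  n <- length(object@winner)
  msg <- character()
  if (length(object@tie) != n || length(object@selectivity) != n ||
      length(object@displayMask) != n)
    msg <- c(msg, "all slots must have one entry per vertex")
  if (any(object@selectivity < -1e-12, na.rm = TRUE))
    msg <- c(msg, "selectivity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RunReport: outcome of a full pipeline run
#'
#' @slot config the validated configuration list used.
#' @slot tables named list of result tables (network minimum-difference,
#'   lag projections, peak-fit table, selectivity and structural
#'   comparisons).
#' @slot maps named list of derived maps (WTA, contrasts).
#' @slot recovery named list of recovery metrics against the injected truth.
#' @slot stages data.frame of per-stage status.
#' @export
setClass("RunReport",
  representation(config = "list", tables = "list", maps = "list",
                 recovery = "list", stages = "data.frame"))
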