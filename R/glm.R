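#' Build a task GLM design matrix
#'
#' One column per condition: the condition's boxcar (or, for duration-0
#' events, impulse train) sampled at the frame times and convolved with the
#' double-gamma HRF; plus an intercept and an optional linear drift column.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param tr repetition time in seconds.
#' @param nFrames number of frames in the run.
#' @param intercept include an intercept column.
#' @param drift include a linear drift column.
#' @return numeric matrix (frames x columns) with attribute "conditions"
#'   naming the task-regressor columns.
#' @examples
#' d <- taskDesign(data.frame(condition = "hand", onset = 0,
#'                            duration = 15.4), runLength = 60)
#' X <- buildDesignMatrix(d, tr = 2.2, nFrames = 27)
#' colnames(X)
#' @export
buildDesignMatrix <- function(design, tr, nFrames, intercept = TRUE,
                              drift = FALSE) {
  ev <- design@events
  conds <- unique(ev$condition)
  if (!length(conds) && !intercept)
    stop("design has no conditions and no intercept was requested")
  times <- (seq_len(nFrames) - 1L) * tr
  hrf <- doubleGammaHRF(seq(0, 32, by = tr))
  cols <- lapply(conds, function(cd) {
    sub <- ev[ev$condition == cd, , drop = FALSE]
    if (!nrow(sub)) stop("condition without events: ", cd)
    stim <- rep(0, nFrames)
    for (e in seq_len(nrow(sub))) {
      if (sub$duration[e] > 0) {
        on <- times >= sub$onset[e] - 1e-9 &
          times < sub$onset[e] + sub$duration[e] - 1e-9
        stim[on] <- 1
      } else {
        k <- round(sub$onset[e] / tr) + 1L
        if (k >= 1L && k <= nFrames) stim[k] <- stim[k] + 1
      }
    }
    convolve(stim, rev(hrf), type = "open")[seq_len(nFrames)]
  })
  X <- do.call(cbind, c(list(), cols))
  if (is.null(X)) X <- matrix(0, nFrames, 0L)
  colnames(X) <- conds
  if (drift) X <- cbind(X, drift = seq_len(nFrames) / nFrames - 0.5)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  attr(X, "conditions") <- conds
  X
}

#' Fit the run-level GLM
#'
#' Ordinary least squares of every vertex time course on the design matrix;
#' t = beta / SE with df = frames - rank, converted to signed Z-scores
#' (clamped at |Z| = 8.2). No autocorrelation prewhitening is applied.
#'
#' @param run a \linkS4class{BoldRun} or vertex x frame matrix.
#' @param X design matrix from `buildDesignMatrix()`.
#' @return A run-level \linkS4class{ActivationMap} over the condition
#'   regressors.
#' @export
fitGLM <- function(run, X) {
  Y <- t(boldMatrix(run))
  if (nrow(Y) != nrow(X)) stop("design matrix does not match the run length")
  if (nrow(X) <= ncol(X))
    stop("more design columns than frames")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  xtxInv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(xtxInv), sigma2))
  tstat <- beta / se
  conds <- attr(X, "conditions")
  if (is.null(conds)) conds <- colnames(X)
  keep <- match(conds, colnames(X))
  b <- t(beta[keep, , drop = FALSE])
  tt <- t(tstat[keep, , drop = FALSE])
  colnames(b) <- colnames(tt) <- conds
  z <- tToZ(tt, df)
  new("ActivationMap", beta = b, tstat = tt, z = z, df = df,
      level = "run",
      degenerate = matrix(FALSE, nrow(b), ncol(b), dimnames = dimnames(b)))
}

#' @rdname fitGLM
#' @param map an ActivationMap.
#' @export
activationZ <- function(map) map@z

#' @rdname fitGLM
#' @export
activationBeta <- function(map) map@beta

#' @rdname fitGLM
#' @export
activationT <- function(map) map@tstat

setMethod("show", "ActivationMap", function(object) {
  cat("ActivationMap (", object@level, " level): ", nrow(object@z),
      " vertices x ", ncol(object@z), " condition(s), df = ", object@df,
      "\n", sep = "")
})

#' Second-level activation map
#'
#' Per-vertex one-sample t-test of run-level betas against zero activation
#' (df = runs - 1), converted to signed Z. Cells with zero between-run
#' variance and non-zero mean are flagged degenerate and excluded (Z = NA);
#' all-zero cells give t = 0.
#'
#' @param runMaps list of run-level \linkS4class{ActivationMap}s with
#'   identical conditions.
#' @return A subject-level \linkS4class{ActivationMap}.
#' @export
secondLevel <- function(runMaps) {
  if (length(runMaps) < 2L) stop("second level needs at least 2 runs")
  betas <- lapply(runMaps, activationBeta)
  d <- dim(betas[[1L]])
  if (!all(vapply(betas, function(b) identical(dim(b), d), logical(1))))
    stop("run maps have mismatched dimensions")
  R <- length(betas)
  arr <- array(unlist(betas), dim = c(d, R))
  mu <- apply(arr, c(1L, 2L), mean)
  s <- apply(arr, c(1L, 2L), sd)
  tt <- matrix(0, d[1L], d[2L], dimnames = dimnames(betas[[1L]]))
  degen <- matrix(FALSE, d[1L], d[2L], dimnames = dimnames(betas[[1L]]))
  nz <- s > 0
  tt[nz] <- (mu / (s / sqrt(R)))[nz]
  degen[!nz & mu != 0] <- TRUE
  z <- tToZ(tt, R - 1L)
  z[degen] <- NA_real_
  tt[degen] <- NA_real_
  new("ActivationMap", beta = mu, tstat = tt, z = z, df = R - 1L,
      level = "subject", degenerate = degen)
}

#' Planning-versus-execution contrast
#'
#' Per-vertex paired t-test across matched runs of the planning beta minus
#' the execution beta, converted to signed Z. Positive Z means more
#' activity during planning than execution.
#'
#' @param runMaps list of run-level \linkS4class{ActivationMap}s containing
#'   both phase conditions.
#' @param planning,execution condition names of the two phases.
#' @return A subject-level \linkS4class{ActivationMap} with the single
#'   condition "planning_gt_execution".
#' @export
planningVsExecution <- function(runMaps, planning = "planning",
                                execution = "execution") {
  if (length(runMaps) < 2L) stop("need at least 2 matched runs")
  diffs <- vapply(runMaps, function(m) {
    b <- activationBeta(m)
    if (!all(c(planning, execution) %in% colnames(b)))
      stop("run map lacks the planning or execution condition")
    b[, planning] - b[, execution]
  }, numeric(nrow(activationBeta(runMaps[[1L]]))))
  st <- colOneSampleT(t(diffs))
  tt <- cbind(planning_gt_execution = st$t)
  degen <- cbind(planning_gt_execution = st$sd == 0 & st$mean != 0)
  tt[st$sd == 0 & st$mean == 0] <- 0
  z <- tToZ(tt, st$df)
  z[degen] <- NA_real_; tt[degen] <- NA_real_
  rownames(tt) <- rownames(z) <- names(diffs[, 1L])
  new("ActivationMap", beta = cbind(planning_gt_execution = st$mean),
      tstat = tt, z = z, df = st$df, level = "subject", degenerate = degen)
}

#' Gaussian smoothing along the axis
#'
#' 1-D Gaussian convolution of a per-vertex map along the axis ordering
#' with reflecting boundaries (mass-conserving: a constant map is
#' unchanged). `sigma = 0` is the identity.
#'
#' @param map numeric vector in axis order.
#' @param sigma kernel standard deviation in axis units.
#' @return smoothed numeric vector.
#' @export
smoothMap <- function(map, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(map)
  n <- length(map)
  r <- ceiling(4 * sigma)
  kern <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  ## reflecting pad
  if (r > n) stop("sigma too large for the map length")
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  padded <- map[idx]
  out <- vapply(seq_len(n), function(i)
    sum(padded[i:(i + 2L * r)] * kern), numeric(1))
  names(out) <- names(map)
  out
}
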