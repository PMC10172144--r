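#' Lagged cross-covariance function
#'
#' Normalized cross-covariance of two internally standardized time series
#' at integer-frame offsets k in [-maxLag, maxLag]:
#' `CCF(k) = (1/n) * sum_t x(t) * y(t + k)` over the valid overlap. A peak
#' at positive k means y's signal occurs later than x's.
#'
#' @param x,y numeric time series of equal length (>= 4 * maxLag).
#' @param maxLag maximum offset in frames (must be < length/2).
#' @param tr repetition time in seconds (carried for lag conversion).
#' @return A \linkS4class{CCFProfile}.
#' @examples
#' x <- sin(seq(0, 6 * pi, length.out = 200))
#' prof <- laggedCCF(x, x, maxLag = 5)
#' ccfValues(prof)[6]  # lag 0 -> 1
#' @export
laggedCCF <- function(x, y, maxLag = 8L, tr = 1) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (maxLag >= n / 2) stop("maxLag must be smaller than half the length")
  if (n < 4L * maxLag)
    stop("time series too short for this lag window (need >= 4 * maxLag)")
  x <- standardizePop(x)
  y <- standardizePop(y)
  lags <- seq.int(-maxLag, maxLag)
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k]) / n
    else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)]) / n
  }, numeric(1))
  new("CCFProfile", lags = as.integer(lags), values = vals, tr = tr)
}

#' @rdname laggedCCF
#' @param prof a CCFProfile.
#' @export
ccfValues <- function(prof) prof@values

#' @rdname laggedCCF
#' @export
ccfLags <- function(prof) prof@lags

setMethod("show", "CCFProfile", function(object) {
  k <- which.max(object@values)
  cat("CCFProfile: lags", min(object@lags), "..", max(object@lags),
      "frames (tr =", object@tr, "s); peak", round(object@values[k], 3),
      "at lag", object@lags[k], "\n")
})

#' Sub-frame lag by three-point parabolic interpolation
#'
#' Refines the integer-frame extremum (maximum) of a cross-covariance
#' profile to a fractional lag: with c-, c0, c+ the CCF at the extremum and
#' its neighbours, the interpolated lag is
#' `(k0 + 0.5 * (c- - c+) / (c- - 2 c0 + c+)) * tr` seconds. Profiles whose
#' extremum sits at the window edge, or with zero curvature, are invalid.
#'
#' @param prof a \linkS4class{CCFProfile}.
#' @return list with `lag` (seconds; NA if invalid), `valid`, `peak` (CCF
#'   value at the integer extremum).
#' @export
parabolicExtremum <- function(prof) {
  v <- prof@values
  k0 <- which.max(v)
  if (k0 == 1L || k0 == length(v))
    return(list(lag = NA_real_, valid = FALSE, peak = v[k0]))
  cm <- v[k0 - 1L]; c0 <- v[k0]; cp <- v[k0 + 1L]
  den <- cm - 2 * c0 + cp
  if (den == 0)
    return(list(lag = NA_real_, valid = FALSE, peak = c0))
  frac <- prof@lags[k0] + 0.5 * (cm - cp) / den
  list(lag = frac * prof@tr, valid = TRUE, peak = c0)
}

#' Time-delay (TD) matrix
#'
#' Pairwise signal time delays in seconds from the parabolic extremum of
#' each pair's lagged cross-covariance. With a labeling, delays are
#' computed between region-mean time courses. The matrix is antisymmetric
#' by construction (one triangle computed, the other negated):
#' `td[i, j] > 0` means element i's signal occurs later than element j's.
#' Pairs whose CCF peak is below `minPeak`, or whose extremum sits at the
#' window edge, are marked invalid.
#'
#' @param x a \linkS4class{BoldRun} or vertex x frame matrix.
#' @param labeling optional per-vertex region labels; if given, the TD
#'   matrix is computed between region-mean time courses.
#' @param maxLag CCF window half-width in frames.
#' @param minPeak validity guard: minimum |CCF| at the extremum.
#' @param tr repetition time in seconds (taken from a BoldRun if absent).
#' @return A \linkS4class{TDMatrix}.
#' @export
tdMatrix <- function(x, labeling = NULL, maxLag = 8L, minPeak = 0.3,
                     tr = NULL) {
  if (is.null(tr)) {
    if (!is(x, "BoldRun")) stop("tr required when x is a matrix")
    tr <- S4Vectors::metadata(x)$tr
  }
  m <- boldMatrix(x)
  if (!is.null(labeling)) {
    lab <- as.character(labeling)
    if (length(lab) != nrow(m))
      stop("labeling must have one entry per vertex (NA = exclude)")
    keep <- !is.na(lab)
    m <- m[keep, , drop = FALSE]
    lab <- lab[keep]
    regs <- unique(lab)
    m <- t(vapply(regs, function(r)
      colMeans(m[lab == r, , drop = FALSE]), numeric(ncol(m))))
    rownames(m) <- regs
  }
  p <- nrow(m)
  if (p < 2L) stop("need at least 2 elements for a TD matrix")
  td <- matrix(NA_real_, p, p, dimnames = list(rownames(m), rownames(m)))
  valid <- matrix(FALSE, p, p, dimnames = dimnames(td))
  diag(td) <- 0; diag(valid) <- TRUE
  for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
    prof <- laggedCCF(m[i, ], m[j, ], maxLag = maxLag, tr = tr)
    ext <- parabolicExtremum(prof)
    if (!ext$valid || abs(ext$peak) < minPeak) next
    ## CCF(i, j) peaks at +d when j lags i by d, so td[j, i] = +lag
    td[j, i] <- ext$lag
    td[i, j] <- -ext$lag
    valid[i, j] <- valid[j, i] <- TRUE
  }
  new("TDMatrix", td = td, valid = valid)
}

#' @rdname tdMatrix
#' @param tdm a TDMatrix.
#' @export
tdValues <- function(tdm) tdm@td

#' @rdname tdMatrix
#' @export
tdValid <- function(tdm) tdm@valid

setMethod("show", "TDMatrix", function(object) {
  cat("TDMatrix:", nrow(object@td), "elements;",
      sum(object@valid[upper.tri(object@valid)]), "of",
      sum(upper.tri(object@valid)), "pairs valid\n")
})

#' Average TD matrices across sessions
#'
#' Element-wise mean over the sessions in which each pair was valid; a pair
#' is valid in the average if it was valid in at least one session.
#'
#' @param tdms list of \linkS4class{TDMatrix} objects of equal dimension.
#' @return A \linkS4class{TDMatrix}.
#' @export
averageTDMatrices <- function(tdms) {
  stopifnot(length(tdms) >= 1L)
  p <- nrow(tdms[[1L]]@td)
  acc <- matrix(0, p, p, dimnames = dimnames(tdms[[1L]]@td))
  cnt <- matrix(0L, p, p, dimnames = dimnames(acc))
  for (tdm in tdms) {
    v <- tdm@valid
    acc[v] <- acc[v] + tdm@td[v]
    cnt <- cnt + v
  }
  td <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  dimnames(td) <- dimnames(acc)
  new("TDMatrix", td = td, valid = cnt > 0L)
}

#' Mean lag projection by region group
#'
#' Row means of the TD matrix over valid entries (the average time shift of
#' each element relative to all others; positive = later), then averaged
#' within region groups (CON, inter-effector, foot, hand, mouth).
#'
#' @param tdm a \linkS4class{TDMatrix}.
#' @param grouping named character mapping the TD matrix row names to
#'   groups; by default the three inter-effector regions are pooled as
#'   "inter" and other motor/CON regions keep their own name.
#' @return named numeric of group mean lags (seconds), with the per-row
#'   means attached as attribute "rowMeans".
#' @export
meanLagProjection <- function(tdm, grouping = NULL) {
  td <- tdm@td; valid <- tdm@valid
  diag(valid) <- FALSE
  rows <- rownames(td)
  if (is.null(grouping)) {
    grouping <- setNames(rows, rows)
    grouping[rows %in% .interRegions] <- "inter"
  }
  rm <- vapply(seq_len(nrow(td)), function(i) {
    v <- valid[i, ]
    if (!any(v)) return(NA_real_)
    mean(td[i, v])
  }, numeric(1))
  names(rm) <- rows
  groups <- unique(unname(grouping[rows]))
  out <- vapply(groups, function(g) {
    idx <- which(grouping[rows] == g)
    if (!length(idx)) stop("empty group ", g)
    mean(rm[idx], na.rm = TRUE)
  }, numeric(1))
  attr(out, "rowMeans") <- rm
  out
}
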