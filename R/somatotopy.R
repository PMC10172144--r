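#' Project vertices onto the axis line
#'
#' Assigns every vertex the ordered (0-based) position of its Euclidean-
#' nearest axis point; exact ties go to the lower index. The same rule maps
#' external coordinates (e.g. cortical stimulation sites) onto the axis.
#'
#' @param vertexCoords numeric matrix (n x 2) of coordinates.
#' @param axisCoords numeric matrix (L x 2) of axis-line coordinates in
#'   dorsal -> ventral order.
#' @return integer vector of 0-based axis positions.
#' @export
projectToAxis <- function(vertexCoords, axisCoords) {
  if (!nrow(axisCoords)) stop("empty axis")
  vertexCoords <- as.matrix(vertexCoords)
  d2 <- outer(rowSums(vertexCoords^2), rep(1, nrow(axisCoords))) -
    2 * vertexCoords %*% t(axisCoords) +
    outer(rep(1, nrow(vertexCoords)), rowSums(axisCoords^2))
  ## guard against tiny negative rounding before which.min ties
  d2 <- round(d2, 9)
  as.integer(apply(d2, 1L, which.min) - 1L)
}

#' Winner-take-all movement map
#'
#' Assigns each vertex the movement with the greatest activation Z; exact
#' ties go to the lowest condition index and are flagged. Selectivity is
#' the margin between the best and second-best Z. An optional top-percent
#' display mask keeps only the most strongly activated vertices.
#'
#' @param zMat numeric matrix (vertex x condition) of activation Z-scores.
#' @param topPercent optional; keep only vertices whose winning Z lies in
#'   the top `topPercent` percent.
#' @return A \linkS4class{WTAMap}.
#' @export
winnerTakeAll <- function(zMat, topPercent = NULL) {
  if (is.null(dim(zMat)) || ncol(zMat) < 2L)
    stop("winner-take-all needs at least 2 conditions")
  if (is.null(colnames(zMat)))
    colnames(zMat) <- paste0("cond", seq_len(ncol(zMat)))
  best <- apply(zMat, 1L, max)
  winIdx <- apply(zMat, 1L, which.max)   # first maximum = lowest index
  tie <- rowSums(zMat == best) > 1L
  second <- vapply(seq_len(nrow(zMat)), function(i)
    max(zMat[i, -winIdx[i]]), numeric(1))
  mask <- rep(TRUE, nrow(zMat))
  if (!is.null(topPercent))
    mask <- best >= quantile(best, 1 - topPercent / 100, names = FALSE)
  new("WTAMap", winner = colnames(zMat)[winIdx], tie = tie,
      selectivity = pmax(best - second, 0), displayMask = mask)
}

#' @rdname winnerTakeAll
#' @param wta a WTAMap.
#' @export
wtaWinner <- function(wta) wta@winner

#' @rdname winnerTakeAll
#' @export
wtaSelectivity <- function(wta) wta@selectivity

#' @rdname winnerTakeAll
#' @export
wtaDisplayMask <- function(wta) wta@displayMask

setMethod("show", "WTAMap", function(object) {
  cat("WTAMap:", length(object@winner), "vertices;",
      sum(object@tie), "ties\n")
  print(table(object@winner))
})

#' Movement selectivity
#'
#' Per-vertex difference between the activation of the most preferred and
#' the second-most preferred movement across the supplied condition set
#' (by default the six centre movements: toes, abdominal, hand, eyelid,
#' tongue, swallowing). Broadly tuned vertices score near zero.
#'
#' @param zMat numeric matrix (vertex x condition) of activation Z-scores
#'   for the configured condition set.
#' @return numeric vector of per-vertex selectivity values (>= 0).
#' @export
movementSelectivity <- function(zMat) {
  if (is.null(dim(zMat)) || ncol(zMat) < 2L)
    stop("selectivity needs at least 2 conditions")
  sorted <- apply(zMat, 1L, function(v) sort(v, decreasing = TRUE)[1:2])
  out <- sorted[1L, ] - sorted[2L, ]
  names(out) <- rownames(zMat)
  out
}

#' Movement coactivation profiles
#'
#' For each region, the mean activation across its vertices per movement (a
#' profile of motor activation strengths); profiles are then correlated
#' between every pair of regions. Regions engaged by the same movements
#' (e.g. the inter-effector regions and the CON) show high profile
#' correlations.
#'
#' @param zMat numeric matrix (vertex x movement) of activation Z-scores.
#' @param labeling per-vertex region labels.
#' @param exclude movements to drop (e.g. motion-distorted conditions);
#'   at least 3 movements must remain.
#' @return list with `profiles` (region x movement) and `correlation`
#'   (region x region; NA where a profile is constant).
#' @export
coactivationProfiles <- function(zMat, labeling, exclude = NULL) {
  keep <- setdiff(colnames(zMat), exclude)
  if (length(keep) < 3L)
    stop("need at least 3 movements after exclusion")
  zMat <- zMat[, keep, drop = FALSE]
  lab <- as.character(labeling)
  regs <- unique(lab[!is.na(lab)])
  prof <- t(vapply(regs, function(r)
    colMeans(zMat[lab == r, , drop = FALSE]), numeric(ncol(zMat))))
  rownames(prof) <- regs
  sds <- apply(prof, 1L, sd)
  cc <- matrix(NA_real_, nrow(prof), nrow(prof),
               dimnames = list(regs, regs))
  ok <- sds > 0
  if (any(ok))
    cc[ok, ok] <- cor(t(prof[ok, , drop = FALSE]))
  list(profiles = prof, correlation = cc)
}

#' LOWESS-smoothed activation profile
#'
#' Locally weighted linear regression (tricube weights, one robustness
#' iteration) of activation against axis position, evaluated at every
#' input position -- the curve-visualization analogue of the Gaussian
#' peak fits.
#'
#' @param positions numeric axis positions (strictly increasing).
#' @param activation numeric activation values.
#' @param span fraction of points used for each local fit, in (0, 1].
#' @return data.frame with columns position and smoothed.
#' @export
lowessProfile <- function(positions, activation, span = 2 / 3) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  n <- length(positions)
  if (length(activation) != n) stop("positions/activation length mismatch")
  if (floor(span * n) < 3L)
    stop("span too small: local fits need at least 3 points")
  lw <- lowess(positions, activation, f = span, iter = 1L)
  data.frame(position = lw$x, smoothed = lw$y)
}
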