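#' Construct the synthetic ground truth
#'
#' Defines the latent-signal structure, temporal lags, spatial activation
#' peaks and noise level that the synthetic generator injects, and that
#' recovery tests check against.
#'
#' Each region is assigned to a network latent signal; its resting signal is
#' `globalWeight * global(t - d) + networkWeight * latent_net(t - d)` where
#' `d` is the region's delay and `networkWeight = sqrt(1 - globalWeight^2)`,
#' so region signals have (approximately) unit variance. Regions sharing a
#' network latent (by default the three inter-effector regions and the CON)
#' are mutually correlated; the shared global latent keeps all pairs weakly
#' correlated, as in real BOLD, which gives the lag estimator a usable
#' cross-covariance peak for every pair.
#'
#' @param strip a \linkS4class{CorticalStrip} (defines which regions exist).
#' @param networkAssignments named character: region -> latent signal name.
#' @param globalWeight loading of every region on the shared global latent,
#'   in [0, 1).
#' @param delays named numeric, per-region signal delay in seconds
#'   (positive = later). The injected pairwise lag for regions i, j is
#'   `delays[i] - delays[j]`, antisymmetric by construction.
#' @param peakParams named list of true spatial activation profiles per
#'   movement: `c(a1, b1, c1)` or `c(a1, b1, c1, a2, b2, c2)` with
#'   amplitudes `a >= 0` and widths `c > 0`, positions in axis units.
#' @param regionTaskAmplitudes optional region x condition matrix of
#'   additional region-level response amplitudes.
#' @param noiseSd white-noise sd added to every vertex time course.
#' @param seed integer root seed; all per-run seeds are derived from it.
#' @return A \linkS4class{SyntheticTruth}.
#' @examples
#' strip <- generateStrip(20)
#' truth <- syntheticTruth(strip, noiseSd = 0.5, seed = 7)
#' pairwiseLags(truth)["CON", "foot"]
#' @export
syntheticTruth <- function(strip,
                           networkAssignments = NULL,
                           globalWeight = 0.6,
                           delays = NULL,
                           peakParams = list(),
                           regionTaskAmplitudes = NULL,
                           noiseSd = 1,
                           seed = 1L) {
  regions <- levels(regionLabels(strip))
  if (is.null(networkAssignments)) {
    networkAssignments <- c(
      foot = "foot", hand = "hand", mouth = "mouth",
      inter_superior = "scan", inter_middle = "scan",
      inter_inferior = "scan", CON = "scan",
      S1_adjacent = "s1", background = "bg")
  }
  networkAssignments <- networkAssignments[names(networkAssignments) %in%
                                             regions]
  if (!all(regions %in% names(networkAssignments)))
    stop("networkAssignments must cover every region on the strip")
  if (globalWeight < 0 || globalWeight >= 1)
    stop("globalWeight must lie in [0, 1)")
  if (is.null(delays)) {
    delays <- setNames(rep(0, length(regions)), regions)
    delays[intersect(.interRegions, regions)] <- 0.4
    if ("CON" %in% regions) delays["CON"] <- 0.8
  }
  delays <- delays[names(delays) %in% regions]
  if (!all(regions %in% names(delays)))
    stop("delays must cover every region on the strip")

  latents <- c("global", sort(unique(unname(networkAssignments))))
  w <- sqrt(1 - globalWeight^2)
  loadings <- matrix(0, length(regions), length(latents),
                     dimnames = list(regions, latents))
  loadings[, "global"] <- globalWeight
  for (r in regions) loadings[r, networkAssignments[[r]]] <- w

  if (is.null(regionTaskAmplitudes))
    regionTaskAmplitudes <- matrix(0, 0L, 0L)
  new("SyntheticTruth", loadings = loadings,
      delays = delays[regions], peakParams = peakParams,
      regionTaskAmplitudes = regionTaskAmplitudes,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Injected pairwise lags
#'
#' The antisymmetric region x region matrix of true time delays implied by
#' the per-region delays: `lag[i, j] = delays[i] - delays[j]` (seconds,
#' positive = region i's signal occurs later).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return numeric matrix.
#' @export
pairwiseLags <- function(truth) {
  d <- truth@delays
  outer(d, d, "-")
}

#' @rdname pairwiseLags
#' @export
truthLoadings <- function(truth) truth@loadings

#' @rdname pairwiseLags
#' @export
truthPeakParams <- function(truth) truth@peakParams

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@loadings), "regions,",
      ncol(object@loadings), "latent signals; noiseSd =", object@noiseSd,
      "\n")
  cat("delays (s):\n"); print(object@delays)
})
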