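#' Fisher-z functional connectivity
#'
#' Pairwise Pearson correlation of vertex time courses, clipped to
#' +/-(1 - 1e-7) and Fisher-transformed (atanh). Vertices with zero
#' temporal variance are masked out; the diagonal is excluded. With several
#' runs, each run's time courses are standardized before concatenation.
#'
#' @param x a \linkS4class{BoldRun}, a vertex x frame matrix, or a list of
#'   either (multiple runs).
#' @return A \linkS4class{ConnectivityMatrix}.
#' @examples
#' m <- matrix(rnorm(200), 10)
#' conn <- fisherConnectivity(m)
#' range(connZ(conn), na.rm = TRUE)
#' @export
fisherConnectivity <- function(x) {
  if (is.list(x) && !is.matrix(x)) {
    mats <- lapply(x, boldMatrix)
    mats <- lapply(mats, function(m) {
      s <- apply(m, 1L, sd)
      sweep(sweep(m, 1L, rowMeans(m)), 1L, ifelse(s > 0, s, 1), "/")
    })
    m <- do.call(cbind, mats)
  } else m <- boldMatrix(x)
  if (ncol(m) < 3L) stop("connectivity needs at least 3 frames")
  keep <- apply(m, 1L, sd) > 0
  n <- nrow(m)
  z <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  mask <- matrix(FALSE, n, n, dimnames = dimnames(z))
  if (!any(keep)) {
    warning("all vertex time courses are constant; matrix fully masked")
    return(new("ConnectivityMatrix", z = z, mask = mask))
  }
  if (sum(!keep) > 0)
    warning(sum(!keep), " constant vertex time course(s) masked out")
  r <- cor(t(m[keep, , drop = FALSE]))
  z[keep, keep] <- fisherZ(r)
  mask[keep, keep] <- TRUE
  diag(z) <- NA_real_
  diag(mask) <- FALSE
  new("ConnectivityMatrix", z = z, mask = mask)
}

#' @rdname fisherConnectivity
#' @param conn a ConnectivityMatrix.
#' @export
connZ <- function(conn) conn@z

#' @rdname fisherConnectivity
#' @export
connMask <- function(conn) conn@mask

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", nrow(object@z), "x", ncol(object@z),
      "vertices;", sum(object@mask), "valid pairs\n")
})

#' Seed maps and the dorsal-to-ventral seed sweep
#'
#' `seedMap()` extracts one seed's Fisher-z map (its row of the
#' connectivity matrix; the seed's own vertex is NA). `seedSweep()` returns
#' one map per axis vertex, ordered dorsal to ventral -- the continuous
#' line-of-seeds analysis.
#'
#' @param conn a \linkS4class{ConnectivityMatrix} over the strip vertices.
#' @param strip the \linkS4class{CorticalStrip} the matrix was computed on.
#' @param seed vertex index (or name) of the seed.
#' @return `seedMap()`: named numeric vector. `seedSweep()`: matrix with one
#'   row per axis vertex (dorsal -> ventral) and one column per vertex.
#' @export
seedMap <- function(conn, seed) {
  z <- conn@z
  if (is.character(seed)) seed <- match(seed, rownames(z))
  if (is.na(seed) || seed < 1L || seed > nrow(z)) stop("invalid seed vertex")
  z[seed, ]
}

#' @rdname seedMap
#' @export
seedSweep <- function(conn, strip) {
  ax <- axisLine(strip)
  if (!length(ax)) stop("strip has an empty axis line")
  out <- conn@z[ax, , drop = FALSE]
  rownames(out) <- rownames(coords(strip))[ax]
  out
}

#' Percentile thresholding of a connectivity map
#'
#' Sets values below the q-th percentile of the valid (non-NA) values to NA.
#' Values exactly equal to the threshold are kept, so a constant map
#' survives in full at any percentile.
#'
#' @param map numeric vector (NA = masked).
#' @param qPercent percentile in (0, 100).
#' @return numeric vector of the same length with sub-threshold entries NA.
#' @examples
#' x <- rnorm(1000)
#' sum(!is.na(percentileThreshold(x, 97)))
#' @export
percentileThreshold <- function(map, qPercent) {
  if (length(qPercent) != 1L || qPercent <= 0 || qPercent >= 100)
    stop("qPercent must lie strictly between 0 and 100")
  valid <- !is.na(map)
  if (!any(valid)) return(map)
  thr <- quantile(map[valid], qPercent / 100, names = FALSE, type = 7)
  map[valid & map < thr] <- NA_real_
  map
}

#' Region-mean functional connectivity
#'
#' Fisher-z correlation between the average time courses of two vertex sets
#' (mean-then-correlate). With several runs, region-mean time courses are
#' standardized per run and concatenated before correlating.
#'
#' @param runs a \linkS4class{BoldRun}, matrix, or list of runs.
#' @param labeling factor/character of per-vertex region labels.
#' @param regionA,regionB region label(s) defining the two vertex sets
#'   (several labels are pooled, e.g. the three inter-effector regions).
#' @return single Fisher-z value.
#' @export
regionMeanConnectivity <- function(runs, labeling, regionA, regionB) {
  if (!is.list(runs) || is.matrix(runs)) runs <- list(runs)
  lab <- as.character(labeling)
  ia <- which(lab %in% regionA)
  ib <- which(lab %in% regionB)
  if (!length(ia) || !length(ib)) stop("empty region in comparison")
  tcs <- lapply(runs, function(run) {
    m <- boldMatrix(run)
    a <- colMeans(m[ia, , drop = FALSE])
    b <- colMeans(m[ib, , drop = FALSE])
    cbind(a = as.numeric(scale(a)), b = as.numeric(scale(b)))
  })
  tc <- do.call(rbind, tcs)
  fisherZ(cor(tc[, "a"], tc[, "b"]))
}

#' Region-seeded connectivity map
#'
#' Fisher-z correlation between the average time course of a vertex set
#' (e.g. the pooled inter-effector regions) and every vertex's time course
#' -- the region-seeded whole-strip connectivity map that the conservative
#' contrast consumes. Seed-region vertices keep their values; with several
#' runs, time courses are standardized per run and concatenated.
#'
#' @inheritParams regionMeanConnectivity
#' @param region region label(s) pooled into the seed.
#' @return named numeric vector of Fisher-z values, one per vertex.
#' @export
regionSeedMap <- function(runs, labeling, region) {
  if (!is.list(runs) || is.matrix(runs)) runs <- list(runs)
  lab <- as.character(labeling)
  idx <- which(lab %in% region)
  if (!length(idx)) stop("empty seed region")
  parts <- lapply(runs, function(run) {
    m <- boldMatrix(run)
    seed <- as.numeric(scale(colMeans(m[idx, , drop = FALSE])))
    list(seed = seed, m = t(scale(t(m))))
  })
  seed <- unlist(lapply(parts, `[[`, "seed"))
  m <- do.call(cbind, lapply(parts, `[[`, "m"))
  out <- fisherZ(as.numeric(cor(seed, t(m))))
  names(out) <- rownames(m)
  out
}

#' Conservative inter-effector contrast
#'
#' Per-vertex difference between a target seed map and the elementwise
#' maximum over competitor seed maps: `target - max(competitors)`. Positive
#' values mark vertices more strongly connected to the target regions than
#' to any competitor region.
#'
#' @param target numeric vector (Fisher-z seed map).
#' @param competitors list of numeric vectors, or a matrix with one column
#'   per competitor map, aligned with `target`.
#' @return numeric vector of the same length as `target`.
#' @export
conservativeContrast <- function(target, competitors) {
  if (is.list(competitors)) competitors <- do.call(cbind, competitors)
  if (is.null(dim(competitors))) competitors <- cbind(competitors)
  if (ncol(competitors) < 1L) stop("at least one competitor map required")
  if (nrow(competitors) != length(target))
    stop("competitor maps are not aligned with the target map")
  if (!is.null(names(target)) && !is.null(rownames(competitors)) &&
      !identical(names(target), rownames(competitors)))
    stop("competitor maps are not aligned with the target map")
  target - apply(competitors, 1L, max)
}

#' Network minimum-difference statistic
#'
#' For each network, the smallest difference between inter-effector
#' connectivity and any effector-specific (foot/hand/mouth) connectivity,
#' computed per subject and averaged across subjects. A large positive
#' value means the network is more strongly connected to the inter-effector
#' regions than to every effector region.
#'
#' @param fcTable data.frame with columns subject, region (one of "inter",
#'   "foot", "hand", "mouth"), network, z.
#' @return data.frame with columns network and minDiff (across-subject
#'   mean); the per-subject matrix (subjects x networks) is attached as
#'   attribute "perSubject".
#' @export
networkMinDifference <- function(fcTable) {
  need <- c("subject", "region", "network", "z")
  if (!all(need %in% names(fcTable)))
    stop("fcTable needs columns subject, region, network, z")
  subjects <- unique(fcTable$subject)
  networks <- unique(fcTable$network)
  per <- matrix(NA_real_, length(subjects), length(networks),
                dimnames = list(as.character(subjects), networks))
  for (s in seq_along(subjects)) for (k in seq_along(networks)) {
    sub <- fcTable[fcTable$subject == subjects[s] &
                     fcTable$network == networks[k], ]
    zi <- sub$z[sub$region == "inter"]
    ze <- vapply(.effectorRegions, function(r) {
      v <- sub$z[sub$region == r]
      if (length(v) != 1L) NA_real_ else v
    }, numeric(1))
    if (length(zi) != 1L || anyNA(ze))
      stop("missing cell for subject ", subjects[s], ", network ",
           networks[k])
    per[s, k] <- min(zi - ze)
  }
  out <- data.frame(network = networks, minDiff = colMeans(per))
  attr(out, "perSubject") <- per
  out
}

#' Paired t-tests with Benjamini-Hochberg correction
#'
#' Two-tailed paired t-tests (df = n - 1) over a declared family of
#' comparisons, with BH false-discovery-rate q-values computed across the
#' declared family size. Zero-variance differences are handled by
#' convention: all-zero differences give t = 0, p = 1; constant non-zero
#' differences are flagged degenerate (p = NA).
#'
#' @param comparisons named list; each element a list/data.frame with paired
#'   vectors `x` and `y`.
#' @param nTests declared family size for the BH correction (defaults to the
#'   number of comparisons).
#' @param alpha significance level for the `sig` flag.
#' @return data.frame with columns comparison, n, t, df, p, q, sig,
#'   degenerate.
#' @examples
#' pairedTTestFDR(list(a = list(x = c(1, 2, 3), y = c(0, 1, 1))))
#' @export
pairedTTestFDR <- function(comparisons, nTests = length(comparisons),
                           alpha = 0.05) {
  if (nTests < length(comparisons))
    stop("declared family size smaller than the number of comparisons")
  res <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    x <- cmp$x; y <- cmp$y
    if (length(x) != length(y)) stop("unpaired samples in ", nm)
    if (length(x) < 2L) stop("paired t-test needs at least 2 subjects")
    d <- x - y
    d <- d[is.finite(d)]          # subjects with missing cells drop out
    if (length(d) < 2L)
      return(data.frame(comparison = nm, n = length(d), t = NA_real_,
                        df = NA_real_, p = NA_real_, degenerate = TRUE))
    n <- length(d)
    degenerate <- FALSE
    if (sd(d) == 0) {
      if (all(d == 0)) { tt <- 0; p <- 1 }
      else { tt <- NA_real_; p <- NA_real_; degenerate <- TRUE }
    } else {
      tt <- mean(d) / (sd(d) / sqrt(n))
      p <- 2 * pt(abs(tt), n - 1L, lower.tail = FALSE)
    }
    data.frame(comparison = nm, n = n, t = tt, df = n - 1L, p = p,
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH", n = max(nTests, nrow(out)))
  out$sig <- !is.na(out$q) & out$q < alpha
  out[, c("comparison", "n", "t", "df", "p", "q", "sig", "degenerate")]
}

#' Region-wise structural comparison
#'
#' Computes per-subject region means of a scalar map (thickness, FA,
#' myelin, ...) and compares the pooled inter-effector mean against each
#' effector-specific region with paired t-tests, FDR-corrected over the
#' three tests.
#'
#' @param maps matrix (subjects x vertices) of scalar values, or a list of
#'   per-subject vectors.
#' @param labeling per-vertex region labels.
#' @param alpha significance level.
#' @return list with `table` (the paired-test table) and `regionMeans`
#'   (subjects x regions matrix).
#' @export
regionScalarCompare <- function(maps, labeling, alpha = 0.05) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  lab <- as.character(labeling)
  groups <- c(list(inter = which(lab %in% .interRegions)),
              lapply(setNames(.effectorRegions, .effectorRegions),
                     function(r) which(lab == r)))
  if (any(lengths(groups) == 0L)) stop("empty region in labeling")
  means <- vapply(groups, function(idx)
    rowMeans(maps[, idx, drop = FALSE]), numeric(nrow(maps)))
  cmps <- lapply(setNames(.effectorRegions,
                          paste0("inter_vs_", .effectorRegions)),
                 function(r) list(x = means[, "inter"], y = means[, r]))
  list(table = pairedTTestFDR(cmps, nTests = 3L, alpha = alpha),
       regionMeans = means)
}
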