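## Internal numeric helpers shared across modules.

.CLIP <- 1 - 1e-7

## Fisher z with correlation clipping at +/-(1 - 1e-7) so r = +/-1 stays
## finite.
fisherZ <- function(r) atanh(pmin(pmax(r, -.CLIP), .CLIP))

## Sign-preserving t -> Z conversion through log-space tail probabilities,
## clamped at |Z| = 8.2 where the normal tail underflows.
tToZ <- function(t, df, clamp = 8.2) {
  z <- sign(t) * qnorm(pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                       lower.tail = FALSE, log.p = TRUE)
  z[is.nan(z)] <- 0
  pmin(pmax(z, -clamp), clamp)
}

## Population standardization (mean 0, sd 1 with the 1/n variance), used by
## the lagged cross-covariance so that |CCF| <= 1.
standardizePop <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) stop("cannot standardize a constant time series")
  x / s
}

## Derived seeds: one root seed, fixed integer offsets per consumer, kept
## within 32-bit range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

## One-sample t statistics down matrix columns; returns list(t, mean, sd).
colOneSampleT <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2L, mu)^2) / (n - 1L))
  list(t = mu / (s / sqrt(n)), mean = mu, sd = s, df = n - 1L)
}

.assertScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

## Extract the vertex x frame matrix from a BoldRun or pass a matrix through.
boldMatrix <- function(x) {
  if (is(x, "BoldRun")) SummarizedExperiment::assay(x, "bold")
  else if (is.matrix(x)) x
  else stop("expected a BoldRun or a vertex x frame matrix")
}
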