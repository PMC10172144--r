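## Small fixtures built in code; every test that needs data generates it
## under a fixed seed.

tinyStrip <- function(perRegion = 10L,
                      offAxis = c(CON = 10L, S1_adjacent = 10L,
                                  background = 10L)) {
  generateStrip(perRegion, offAxis = offAxis)
}

## A strip carrying only the six motor regions.
motorOnlyStrip <- function(perRegion = 10L) {
  generateStrip(perRegion, offAxis = c(CON = 0L, S1_adjacent = 0L,
                                       background = 0L))
}

## Gaussian profile evaluator mirroring the model definition (independent
## of the fitting code path).
gaussProfile <- function(p, x) {
  out <- p[1] * exp(-((x - p[2]) / p[3])^2)
  if (length(p) == 6) out <- out + p[4] * exp(-((x - p[5]) / p[6])^2)
  out
}

## Brute-force Pearson + atanh connectivity oracle.
bruteFisher <- function(m, clip = 1 - 1e-7) {
  n <- nrow(m)
  z <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- cor(m[i, ], m[j, ])
    z[i, j] <- atanh(min(max(r, -clip), clip))
  }
  z
}

## Brute-force lagged cross-covariance oracle (double loop).
bruteCCF <- function(x, y, maxLag) {
  n <- length(x)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  vapply(-maxLag:maxLag, function(k) {
    acc <- 0
    for (t in seq_len(n)) {
      u <- t + k
      if (u >= 1 && u <= n) acc <- acc + x[t] * y[u]
    }
    acc / n
  }, numeric(1))
}
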