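# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Periodogram fraction of power inside [lo, hi] Hz, from first principles.
oracleBandPower <- function(x, lo, hi, trS) {
  n <- length(x)
  x <- x - mean(x)
  sp <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) / (n * trS)
  half <- freqs > 0 & freqs <= 1 / (2 * trS)
  sum(sp[half & freqs >= lo & freqs <= hi]) / sum(sp[half])
}

# Two-pass Pearson correlation + atanh.
oraclePearsonZ <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  r <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  atanh(r)
}

# Normal-equations least squares.
oracleOls <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Brute-force Benjamini-Hochberg step-up adjustment.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two series with an exact sample Pearson correlation.
exactCorrPair <- function(n, r, seed = 1) {
  set.seed(seed)
  u <- rnorm(n); u <- u - mean(u); u <- u / sqrt(sum(u^2))
  v <- rnorm(n); v <- v - mean(v)
  v <- v - sum(u * v) * u
  v <- v / sqrt(sum(v^2))
  cbind(a = u, b = r * u + sqrt(1 - r^2) * v)
}
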