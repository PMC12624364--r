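# Internal numerical helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so package functions never disturb user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
childSeeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# Remove a least-squares linear trend (including mean).
detrendLinear <- function(x) {
  n <- length(x)
  t0 <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t0 * (sum(t0 * x) / sum(t0 * t0))
}

# Zero-phase 4th-order Butterworth band-pass after linear detrend; demeaned.
butterBandpass <- function(x, loHz, hiHz, trS) {
  fs <- 1 / trS
  nyq <- fs / 2
  stopIfNot(loHz > 0 && hiHz > loHz && hiHz < nyq,
            sprintf("pass band must satisfy 0 < lo < hi < Nyquist (%.4g Hz)", nyq))
  flt <- signal::butter(4, c(loHz, hiHz) / nyq, type = "pass")
  minLen <- 3 * (length(flt$b) - 1)
  stopIfNot(length(x) >= minLen,
            sprintf("series too short for the filter (need >= %d frames)", minLen))
  y <- signal::filtfilt(flt, detrendLinear(x))
  y - mean(y)
}

# Fraction of periodogram power inside [loHz, hiHz] (rectangle inclusive).
bandPowerFraction <- function(x, loHz, hiHz, trS) {
  n <- length(x)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1 / trS),
                          taper = 0, detrend = FALSE, demean = TRUE,
                          plot = FALSE)
  inband <- sp$freq >= loHz & sp$freq <= hiHz
  sum(sp$spec[inband]) / sum(sp$spec)
}

# 1D Gaussian kernel matrix (n x n) for convolution along one axis,
# sigma in voxel units; truncated at 4 sigma. Rows are unnormalized so that
# mask renormalization handles edges.
gaussKernelMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= ceiling(4 * sigmaVox), exp(-d^2 / (2 * sigmaVox^2)), 0)
  })
  K / sum(exp(-(-ceiling(4 * sigmaVox):ceiling(4 * sigmaVox))^2 /
              (2 * sigmaVox^2)))
}

# Separable 3D Gaussian smoothing of one volume (no masking).
smooth3d <- function(vol, Kx, Ky, Kz) {
  d <- dim(vol)
  # along x: (nx, ny*nz)
  m <- Kx %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  # along y: permute so y is first
  vol <- aperm(vol, c(2, 1, 3))
  m <- Ky %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # along z
  vol <- aperm(vol, c(3, 1, 2))
  m <- Kz %*% matrix(vol, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# Flatten the 4D array to frames x voxels and back.
framesByVoxels <- function(arr4d) {
  d <- dim(arr4d)
  t(matrix(arr4d, prod(d[1:3]), d[4]))
}

voxelsTo4d <- function(mat, grid) {
  array(t(mat), c(grid, nrow(mat)))
}
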