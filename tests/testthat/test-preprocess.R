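test_that("motion expansion yields the 18-parameter set in order", {
  z <- matrix(0, 5, 6)
  expect_equal(expandMotion(z), matrix(0, 5, 18), ignore_attr = TRUE)
  m <- matrix(0, 4, 6)
  m[, 1] <- c(0, 1, 2, 3)
  X <- expandMotion(m)
  expect_equal(ncol(X), 18L)
  expect_equal(unname(X[, 7]), c(0, 1, 1, 1))    # backward difference
  expect_equal(unname(X[, 13]), c(0, 1, 4, 9))   # square of the parameter
  m[1, 2] <- NA
  expect_error(expandMotion(m), "non-finite")
})

test_that("FD follows the sum-of-absolute-differences convention", {
  m <- matrix(0, 4, 6)
  expect_equal(computeFD(m), rep(0, 4))
  m[3:4, 2] <- 0.25                      # single-axis 0.25 mm step at frame 3
  expect_equal(computeFD(m), c(0, 0, 0.25, 0))
  r <- matrix(0, 3, 6)
  r[2:3, 5] <- 0.002                     # 0.002 rad step, 50 mm radius
  expect_equal(computeFD(r, headRadiusMm = 50), c(0, 0.1, 0))
  expect_error(computeFD(m[1, , drop = FALSE]), ">= 2 frames")
})

test_that("FD and derivatives ignore constant offsets; squares do not", {
  set.seed(8)
  m <- matrix(rnorm(30 * 6, sd = 0.05), 30, 6)
  mOff <- sweep(m, 2, rep(0.7, 6), "+")
  expect_equal(computeFD(m), computeFD(mOff))
  a <- expandMotion(m); b <- expandMotion(mOff)
  expect_equal(a[, 7:12], b[, 7:12])
  expect_false(isTRUE(all.equal(a[, 13:18], b[, 13:18])))
})

test_that("censoring marks strictly-above-threshold frames", {
  cd <- censorDesign(c(0, 0.3, 0.1), thresholdMm = 0.25, trS = 2)
  expect_equal(ncol(cd$spikes), 1L)
  expect_equal(which(cd$spikes[, 1] == 1), 2L)
  expect_equal(censoredFraction(cd$censor), 1 / 3)
  cd2 <- censorDesign(c(0, 0.2, 0.1), 0.25, 2)
  expect_equal(ncol(cd2$spikes), 0L)
  expect_true(all(keepMask(cd2$censor)))
  cd3 <- censorDesign(c(0, 0.25), 0.25, 2)   # boundary: not censored
  expect_true(all(keepMask(cd3$censor)))
})

test_that("inclusion rules reproduce the threshold arithmetic", {
  mk <- function(nFrames, nCensored, trS) {
    fd <- c(0, rep(0.1, nFrames - 1))
    fd[seq_len(nCensored) + 1] <- 0.3
    censorDesign(fd, 0.25, trS)$censor
  }
  a <- checkInclusion(mk(150, 30, 2))        # 20% censored, 240 s left
  expect_true(a$include)
  b <- checkInclusion(mk(150, 40, 2))        # 26.7% censored
  expect_false(b$include)
  expect_match(b$reasons, "fraction", all = FALSE)
  c3 <- checkInclusion(mk(130, 11, 2))       # 238 s < 240 s
  expect_false(c3$include)
  expect_match(c3$reasons, "remaining", all = FALSE)
})

test_that("nuisance regression removes design signal and keeps voxel means", {
  set.seed(3)
  n <- 60
  mot <- makeMotionTrace(n, jitterSd = 0.01, seed = 5)
  X <- suppressMessages(nuisanceDesign(mot))
  grid <- c(3L, 3L, 3L)
  # voxel series = design column + constant
  arr <- array(rep(X[, "mot_1"] * 4 + 7, each = prod(grid)),
               c(grid, n))
  b <- BoldRun(arr, trS = 2)
  out <- nuisanceRegress(b, X)
  # residual is flat at the voxel's own temporal mean
  vm <- mean(X[, "mot_1"] * 4 + 7)
  expect_true(max(abs(boldData(out) - vm)) < 1e-8)
  # intercept-only design: identity
  arr2 <- array(rnorm(prod(grid) * n), c(grid, n))
  b2 <- BoldRun(arr2, trS = 2)
  out2 <- nuisanceRegress(b2, cbind(intercept = rep(1, n)))
  expect_equal(boldData(out2), arr2, tolerance = 1e-12)
  # residual orthogonality to every column
  out3 <- nuisanceRegress(b2, X)
  res <- rsCVR:::framesByVoxels(boldData(out3))
  res <- sweep(res, 2, colMeans(res))
  ip <- crossprod(X, res)
  expect_lt(max(abs(ip)) / max(abs(res)), 1e-6)
})

test_that("spike regression equals frame deletion at kept frames", {
  set.seed(2)
  n <- 60
  mot <- makeMotionTrace(n, spikeFrames = c(10, 25), spikeAmpMm = 0.6,
                         jitterSd = 0.001, seed = 3)
  fd <- computeFD(mot)
  cd <- censorDesign(fd, 0.25, 2)
  expect_gt(ncol(cd$spikes), 0)
  X <- suppressMessages(nuisanceDesign(mot, cd$spikes))
  y <- rnorm(n)
  rSpike <- qr.resid(qr(X), y)
  Xn <- X[, !grepl("^spike", colnames(X)), drop = FALSE]
  keep <- keepMask(cd$censor)
  rDel <- qr.resid(qr(Xn[keep, , drop = FALSE]), y[keep])
  expect_lt(max(abs(rSpike[keep] - rDel)), 1e-8)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  n <- 20
  X <- cbind(intercept = rep(1, n), a = 1:n, b = 2 * (1:n))
  b <- BoldRun(array(rnorm(8 * n), c(2, 2, 2, n)), trS = 2)
  expect_error(nuisanceRegress(b, X), "collinear")
})

test_that("Gaussian smoothing is renormalized, local and optional", {
  grid <- c(15L, 15L, 15L)
  mask <- array(FALSE, grid); mask[4:12, 4:12, 4:12] <- TRUE
  arr <- array(5, c(grid, 2))
  b <- BoldRun(arr, trS = 2, voxelSizeMm = 4, mask = mask)
  expect_identical(smoothGaussian(b, 0), b)
  sm <- smoothGaussian(b, 8)
  expect_lt(max(abs(boldData(sm)[mask] - 5)), 1e-6)
  # conservation of the in-mask mean of a constant image is exact
  expect_equal(mean(boldData(sm)[, , , 1][mask]), 5, tolerance = 1e-12)
  # impulse response matches the closed-form kernel within 1%
  arr2 <- array(0, c(grid, 2)); arr2[8, 8, 8, ] <- 1
  full <- array(TRUE, grid)
  b2 <- BoldRun(arr2, trS = 2, voxelSizeMm = 4, mask = full)
  sm2 <- smoothGaussian(b2, 8)
  sig <- 8 / (2 * sqrt(2 * log(2))) / 4
  xs <- 5:11
  theo <- exp(-((xs - 8))^2 / (2 * sig^2)) * boldData(sm2)[8, 8, 8, 1]
  prof <- boldData(sm2)[xs, 8, 8, 1]
  expect_lt(max(abs(prof - theo)) / max(theo), 0.01)
  expect_warning(smoothGaussian(b2, 2), "below the voxel size")
})
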