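test_that("the global signal is a masked spatial mean", {
  grid <- c(3L, 3L, 3L)
  n <- 10
  series <- rnorm(n)
  arr <- array(rep(series, each = prod(grid)), c(grid, n))
  b <- BoldRun(arr, trS = 2)
  expect_equal(globalSignal(b), series)
  # two-voxel mask: arithmetic mean of the two series
  arr2 <- array(rnorm(prod(grid) * n), c(grid, n))
  b2 <- BoldRun(arr2, trS = 2)
  m <- array(FALSE, grid); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(globalSignal(b2, m), (arr2[1, 1, 1, ] + arr2[2, 2, 2, ]) / 2)
  # invariance to voxels outside the mask
  arr3 <- arr2; arr3[3, 3, 3, ] <- arr3[3, 3, 3, ] + 100
  expect_equal(globalSignal(BoldRun(arr3, trS = 2), m),
               globalSignal(b2, m))
  expect_error(globalSignal(b2, array(FALSE, grid)), "empty")
})

test_that("the band-pass keeps in-band and rejects out-of-band sinusoids", {
  t <- (0:149) * 2.5
  inband <- sin(2 * pi * 0.03 * t)
  y <- bandpass(inband, 0.02, 0.04, 2.5)
  fit <- lm(y ~ sin(2 * pi * 0.03 * t) + cos(2 * pi * 0.03 * t))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.05)
  out <- sin(2 * pi * 0.1 * t)
  y2 <- bandpass(out, 0.02, 0.04, 2.5)
  fit2 <- lm(y2 ~ sin(2 * pi * 0.1 * t) + cos(2 * pi * 0.1 * t))
  expect_lt(sqrt(sum(coef(fit2)[2:3]^2)), 0.1)
  expect_lt(max(abs(bandpass(rep(3, 150), 0.02, 0.04, 2.5))), 1e-9)
  expect_error(bandpass(rnorm(10), 0.02, 0.04, 2.5), "too short")
})

test_that("voxel-wise CVR slopes are OLS slopes on the surrogate", {
  s <- makeCo2Surrogate(150, 2.5, seed = 1)
  grid <- c(2L, 2L, 2L)
  arr <- array(0, c(grid, 150))
  arr[1, 1, 1, ] <- 2 * s + 5
  arr[2, 1, 1, ] <- -s
  b <- BoldRun(arr, trS = 2.5)
  beta <- cvrBetaMap(b, s)
  expect_equal(beta[1, 1, 1], 2, tolerance = 1e-10)
  expect_equal(beta[2, 1, 1], -1, tolerance = 1e-10)
  # a voxel carrying exactly the surrogate regresses to slope 1
  arr[1, 2, 1, ] <- s
  expect_equal(cvrBetaMap(BoldRun(arr, trS = 2.5), s)[1, 2, 1], 1,
               tolerance = 1e-10)
  # independent-noise voxel: slope within OLS sampling bounds
  set.seed(4)
  noise <- rnorm(150, sd = 3)
  arr[2, 2, 1, ] <- noise
  b3 <- cvrBetaMap(BoldRun(arr, trS = 2.5), s)[2, 2, 1]
  expect_lt(abs(b3), 3 * 3 / (sd(s) * sqrt(150)))
  expect_error(cvrBetaMap(b, rep(1, 150)), "zero variance")
})

test_that("inverse-tSNR exclusion takes the strictly-above-percentile tail", {
  set.seed(1)
  arr <- array(rnorm(100 * 50, 1000, 1), c(100, 1, 1, 50))
  arr[3, 1, 1, ] <- rnorm(50, 1000, 100)
  arr[77, 1, 1, ] <- rnorm(50, 1000, 100)
  ex <- itsnrExclusion(BoldRun(arr, trS = 2))
  expect_equal(which(ex), c(3L, 77L))
  # identical voxels: nothing strictly above the percentile
  one <- rnorm(50, 1000, 5)
  arr2 <- array(rep(one, each = 64), c(4, 4, 4, 50))
  expect_equal(sum(itsnrExclusion(BoldRun(arr2, trS = 2))), 0L)
  # random data: about 2% excluded
  set.seed(2)
  arr3 <- array(rnorm(1000 * 40, 500, abs(rnorm(1000, 10, 3))),
                c(10, 10, 10, 40))
  frac <- mean(itsnrExclusion(BoldRun(arr3, trS = 2)))
  expect_gte(frac, 0.01); expect_lte(frac, 0.03)
})

test_that("rCVR normalization is a ratio to the reference tissue", {
  grid <- c(6L, 6L, 6L)
  geom <- phantomGeometry(grid, 5)
  beta <- array(1.0, grid)
  beta[wmMask(geom$masks)] <- 0.5
  cvr <- normalizeCvr(beta, geom$masks)
  expect_equal(referenceBeta(cvr), 0.5)
  expect_true(all(abs(rcvrVolume(cvr)[gmMask(geom$masks)] - 2) < 1e-12))
  # uniform scaling cancels
  cvr2 <- normalizeCvr(beta * 3.3, geom$masks)
  expect_equal(rcvrVolume(cvr2), rcvrVolume(cvr), tolerance = 1e-12)
  # zero reference is degenerate
  beta0 <- array(rnorm(prod(grid), 0, 1), grid)
  beta0[wmMask(geom$masks)] <- 0
  expect_error(normalizeCvr(beta0, geom$masks), "degenerate reference")
})

test_that("regional averaging respects exclusions and flags empty regions", {
  grid <- c(6L, 6L, 6L)
  geom <- phantomGeometry(grid, 5)
  vol <- array(7, grid)
  avg <- regionalAverage(vol, geom$atlas)
  expect_true(all(avg == 7))
  # 3 voxels (1,2,3) with the middle one excluded -> mean 2
  labs <- array(0L, c(3L, 1L, 1L))
  labs[] <- 1L
  atlas <- AtlasLabels(labs)
  v <- array(c(1, 2, 3), c(3, 1, 1))
  ex <- array(c(FALSE, TRUE, FALSE), c(3, 1, 1))
  expect_equal(unname(regionalAverage(v, atlas, ex)), 2)
  # fully excluded region is NA, not 0
  exAll <- array(TRUE, c(3, 1, 1))
  expect_true(is.na(regionalAverage(v, atlas, exAll)))
})

test_that("motion QC reports exact and null correlations", {
  set.seed(6)
  fd <- runif(40, 0.05, 0.3)
  gm <- 2 * fd + 1
  reg <- matrix(rnorm(40 * 3), 40, 3,
                dimnames = list(NULL, paste0("r", 1:3)))
  qc <- motionQc(reg, gm, fd)
  expect_equal(qc$global$r, 1, tolerance = 1e-12)
  qc2 <- motionQc(reg[1:3, ], gm[1:3], fd[1:3])
  expect_match(qc2$global$flag, "low_power")
  qc3 <- motionQc(reg, rep(1, 40), fd)
  expect_true(is.na(qc3$global$r))
  expect_match(qc3$global$flag, "undefined_correlation")
})

test_that("rCVR is invariant to global rescaling of the 4D series", {
  truth <- smallTruth(seed = 4)
  sub <- makeSubject(truth, smallAcq(noiseSd = 20), seed = 5)
  cfg <- exactConfig()
  pp <- quietPreprocess(sub$bold, sub$motion, cfg)
  rc1 <- computeRcvr(pp$bold, sub$masks, sub$atlas, cfg)
  scaled <- BoldRun(boldData(pp$bold) * 4.2, trS = trS(pp$bold),
                    voxelSizeMm = voxelSizeMm(pp$bold),
                    mask = brainMask(pp$bold))
  rc2 <- computeRcvr(scaled, sub$masks, sub$atlas, cfg)
  expect_lt(max(abs(rc2$regional - rc1$regional) / abs(rc1$regional)), 1e-9)
})

test_that("noiseless end-to-end recovery matches true gain ratios", {
  truth <- smallTruth(seed = 9)
  sub <- makeSubject(truth, smallAcq(), seed = 2, neuronalAmp = 0)
  cfg <- exactConfig()
  pp <- quietPreprocess(sub$bold, sub$motion, cfg)
  rc <- computeRcvr(pp$bold, sub$masks, sub$atlas, cfg)
  expect_lt(max(abs(rc$regional -
                      truth$regionalCvrGain / truth$wmCvrGain)), 1e-6)
})
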