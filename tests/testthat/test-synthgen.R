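test_that("CO2 surrogate is band-limited, standardized and deterministic", {
  s <- makeCo2Surrogate(150, 2.5, c(0.02, 0.04), seed = 7)
  expect_length(s, 150)
  expect_lt(abs(mean(s)), 1e-6)
  expect_lt(abs(sd(s) - 1), 1e-6)
  expect_gte(oracleBandPower(s, 0.02, 0.04, 2.5), 0.95)
  expect_identical(s, makeCo2Surrogate(150, 2.5, c(0.02, 0.04), seed = 7))
  expect_false(identical(s, makeCo2Surrogate(150, 2.5, seed = 8)))
  # several seeds stay band-limited
  for (sd. in 1:5)
    expect_gte(oracleBandPower(makeCo2Surrogate(200, 2, seed = sd.),
                               0.02, 0.04, 2), 0.95)
})

test_that("surrogate rejects bands outside (0, Nyquist)", {
  expect_error(makeCo2Surrogate(150, 2.5, c(0.02, 0.3)), "invalid band")
  expect_error(makeCo2Surrogate(150, 2.5, c(0, 0.04)), "invalid band")
})

test_that("motion traces realize the requested FD excursions", {
  m0 <- makeMotionTrace(50)
  expect_true(all(computeFD(m0) == 0))
  m1 <- makeMotionTrace(50, spikeFrames = 10, spikeAmpMm = 0.5)
  fd <- computeFD(m1)
  expect_gte(fd[10], 0.495)
  expect_true(all(fd[-10] < 0.25))
  # pure drift: constant backward differences
  m2 <- makeMotionTrace(50, driftMmPerFrame = 0.01)
  fd2 <- computeFD(m2)
  expect_true(all(abs(fd2[-1] - 0.01) < 1e-12))
  expect_error(makeMotionTrace(50, spikeFrames = 1), "first frame")
})

test_that("noiseless subjects compose analytically with the rCVR stages", {
  truth <- smallTruth(seed = 4)
  truth$regionalCvrGain[] <- 2 * truth$wmCvrGain
  sub <- makeSubject(truth, smallAcq(), seed = 5, neuronalAmp = 0)
  cfg <- exactConfig()
  pp <- quietPreprocess(sub$bold, sub$motion, cfg)
  rc <- computeRcvr(pp$bold, sub$masks, sub$atlas, cfg)
  expect_true(all(abs(rc$regional - 2) < 1e-9))
})

test_that("zero surrogate and zero noise give a constant baseline run", {
  truth <- smallTruth(seed = 4)
  acq <- smallAcq()
  sub <- makeSubject(truth, acq, surrogate = numeric(acq$nFrames),
                     seed = 5, neuronalAmp = 0)
  expect_true(all(boldData(sub$bold) == acq$baselineIntensity))
})

test_that("subject synthesis is deterministic in the seed", {
  truth <- smallTruth(seed = 4)
  a <- makeSubject(truth, smallAcq(noiseSd = 20), seed = 11)
  b <- makeSubject(truth, smallAcq(noiseSd = 20), seed = 11)
  expect_identical(boldData(a$bold), boldData(b$bold))
  expect_identical(a$motion, b$motion)
})

test_that("neuronal signals live in their band and carry the target correlation", {
  C <- makeNetworkCorr(6, rho = 0.4, blockSize = 3)
  N <- rsCVR:::makeNeuronalSignals(400, 2, C, seed = 3)
  for (j in 1:6)
    expect_gte(oracleBandPower(N[, j], 0.008, 0.1, 2), 0.95)
  est <- cor(N)
  expect_lt(max(abs(est - C)), 0.15)  # sampling noise at T=400
})

test_that("reference cohort reproduces the four-cell composition", {
  coh <- makeCohort(referenceCohortConfig(), seed = 2)
  ph <- coh$phenotypes
  expect_equal(nrow(ph), 294)
  expect_equal(sum(ph$sex == "F" & ph$diagnosis == "NA"), 74)
  expect_equal(sum(ph$sex == "F" & ph$diagnosis == "ASD"), 16)
  expect_equal(sum(ph$sex == "M" & ph$diagnosis == "ASD"), 79)
  expect_equal(dim(coh$features), c(91, 294))
})

test_that("null cohorts have no systematic group differences", {
  coh <- makeCohort(cohortConfig(cells = c(MA = 40, FA = 40, MN = 40,
                                           FN = 40), nSites = 1,
                                 nRegions = 20), seed = 9)
  ph <- coh$phenotypes
  d <- rowMeans(coh$features[, ph$diagnosis == "ASD"]) -
    rowMeans(coh$features[, ph$diagnosis == "NA"])
  # group mean difference is pure subject noise: SE = 0.75*sqrt(2/80)
  expect_lt(max(abs(d)), 5 * 0.75 * sqrt(2 / 80))
})

test_that("injected interaction equals its closed-form cell-mean contrast", {
  g <- 0.31
  ge <- matrix(0, 4, 3)
  ge[2, 3] <- g
  coh <- makeCohort(cohortConfig(cells = c(MA = 6, FA = 6, MN = 6, FN = 6),
                                 nSites = 1, nRegions = 4, groupEffects = ge,
                                 subjectSd = 0), seed = 3)
  ph <- coh$phenotypes
  mu <- function(dx, sx) mean(coh$features[2, ph$diagnosis == dx & ph$sex == sx])
  contrast <- (mu("ASD", "M") + mu("NA", "F") - mu("ASD", "F") -
                 mu("NA", "M")) / 4
  expect_equal(contrast, g, tolerance = 1e-12)
  # and the GLM recovers it exactly on the noiseless design
  X <- buildDesign(ph, c("intercept", "diagnosis", "sex", "dx_by_sex"))
  fit <- fitGlm(coh$features[2, ], X)
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "dx_by_sex"],
               g, tolerance = 1e-12)
})

test_that("effect patterns referencing unknown regions are rejected", {
  expect_error(referenceCohortConfig("interaction", effectRegions = c(1L, 99L)),
               "unknown region")
})

test_that("the truth manifest round-trips losslessly through JSON", {
  coh <- makeCohort(cohortConfig(cells = c(MA = 3, FA = 3, MN = 3, FN = 3),
                                 nSites = 2, nRegions = 5), seed = 21)
  path <- tempfile(fileext = ".json")
  writeCohortTruth(coh$truth, path)
  back <- readCohortTruth(path)
  expect_equal(back$baseRcvr, coh$truth$baseRcvr)
  expect_equal(back$bioFeatures, unname(coh$truth$bioFeatures),
               ignore_attr = TRUE)
  expect_equal(back$siteAdditive, coh$truth$siteAdditive,
               ignore_attr = TRUE)
  expect_equal(back$siteMultiplicative, coh$truth$siteMultiplicative,
               ignore_attr = TRUE)
  expect_equal(back$rngSeed, coh$truth$rngSeed)
})
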