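#' Acquisition configuration for synthetic BOLD runs
#'
#' Defaults describe a desk-scale acquisition consistent with the multi-site
#' harmonization window used for cohort selection (TR between 2 and 3 s):
#' 150 frames at TR 2.5 s on a 20x20x20 grid of 4 mm voxels, baseline
#' intensity 1000 with temporal noise SD 20 (tSNR of about 50).
#'
#' @param nFrames number of time frames (>= 2).
#' @param trS repetition time, seconds, in (0, 10].
#' @param gridShape integer vector of 3 grid dimensions (each >= 4).
#' @param voxelSizeMm isotropic voxel edge length, millimetres.
#' @param noiseSd additive thermal-noise SD, BOLD units (>= 0).
#' @param baselineIntensity mean signal level, BOLD units.
#' @return A named list of class `acquisitionConfig`.
#' @export
acquisitionConfig <- function(nFrames = 150L, trS = 2.5,
                              gridShape = c(20L, 20L, 20L),
                              voxelSizeMm = 4, noiseSd = 20,
                              baselineIntensity = 1000) {
  stopIfNot(nFrames >= 2, "nFrames must be >= 2")
  stopIfNot(trS > 0 && trS <= 10, "trS must be in (0, 10] seconds")
  stopIfNot(length(gridShape) == 3 && all(gridShape >= 4),
            "gridShape needs 3 dimensions, each >= 4")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  structure(list(nFrames = as.integer(nFrames), trS = trS,
                 gridShape = as.integer(gridShape),
                 voxelSizeMm = voxelSizeMm, noiseSd = noiseSd,
                 baselineIntensity = baselineIntensity),
            class = "acquisitionConfig")
}

#' Spherical-shell phantom geometry: tissue masks and a parcellation
#'
#' Builds a nested-sphere head phantom on the given grid: a central CSF
#' core, a white-matter shell, and a gray-matter shell, with the gray-matter
#' shell partitioned into `nRegions` spatially coherent parcels (angular
#' wedges within thin axial slabs, chunked to near-equal voxel counts).
#'
#' @param gridShape integer vector of 3 grid dimensions.
#' @param nRegions number of gray-matter parcels (default 91, matching the
#'   dimensionality of a standard cortical/subcortical gray-matter atlas).
#' @return list with elements `masks` ([SegmentationMasks-class]) and
#'   `atlas` ([AtlasLabels-class]).
#' @export
phantomGeometry <- function(gridShape = c(20L, 20L, 20L), nRegions = 91L) {
  n <- min(gridShape)
  ctr <- (gridShape + 1) / 2
  g <- expand.grid(x = seq_len(gridShape[1]), y = seq_len(gridShape[2]),
                   z = seq_len(gridShape[3]))
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  rBrain <- 0.45 * n; rWm <- 0.28 * n; rCsf <- max(0.10 * n, 0.9)
  mk <- function(v) array(v, gridShape)
  csf <- mk(r <= rCsf)
  wm  <- mk(r > rCsf & r <= rWm)
  gm  <- mk(r > rWm & r <= rBrain)
  stopIfNot(sum(gm) >= nRegions,
            "grid too small for the requested number of parcels")
  # order GM voxels by axial position then azimuth, split into equal chunks
  idx <- which(gm)
  dz <- g$z[idx] - ctr[3]
  az <- atan2(g$y[idx] - ctr[2], g$x[idx] - ctr[1])
  ord <- order(dz, az)
  labels <- array(0L, gridShape)
  chunks <- split(idx[ord],
                  ceiling(seq_along(ord) / (length(ord) / nRegions)))
  for (k in seq_along(chunks)) labels[chunks[[k]]] <- as.integer(k)
  list(masks = SegmentationMasks(gm, wm, csf), atlas = AtlasLabels(labels))
}

#' Band-limited stochastic CO2 surrogate series
#'
#' Filtered Gaussian noise: white noise passed through a zero-phase
#' Butterworth band-pass (applied twice to concentrate spectral power),
#' then standardized to zero mean and unit variance. Mimics the stochastic
#' character of respiratory volume variation during natural breathing
#' (0.02-0.04 Hz by default).
#'
#' @param nFrames number of frames (>= 2; at least `2/(lo*trS)` recommended
#'   so several cycles of the slowest in-band component are observed).
#' @param trS repetition time, seconds.
#' @param bandHz length-2 pass band in Hz; must lie inside (0, Nyquist).
#' @param seed integer seed; same seed, same series.
#' @return numeric series of length `nFrames`, mean 0, SD 1.
#' @export
makeCo2Surrogate <- function(nFrames, trS = 2.5, bandHz = c(0.02, 0.04),
                             seed = 1L) {
  stopIfNot(nFrames >= 2, "nFrames must be >= 2")
  nyq <- 1 / (2 * trS)
  if (!(bandHz[1] > 0 && bandHz[2] > bandHz[1] && bandHz[2] < nyq))
    stop(sprintf("invalid band: [%g, %g] Hz must lie inside (0, %g) Hz",
                 bandHz[1], bandHz[2], nyq), call. = FALSE)
  x <- withSeed(seed, rnorm(nFrames))
  y <- butterBandpass(x, bandHz[1], bandHz[2], trS)
  y <- butterBandpass(y, bandHz[1], bandHz[2], trS)
  y <- y - mean(y)
  y / sd(y)
}

#' Rigid-body motion trace with step spikes and linear drift
#'
#' Produces a 6-column trace (3 translations in mm, 3 rotations in radians).
#' Each spike is a sustained step of `spikeAmpMm` on the x translation at
#' the requested frame, so framewise displacement shows a single excursion
#' there; drift is linear on the x translation.
#'
#' @param nFrames number of frames.
#' @param spikeFrames 1-based frame indices in `[2, nFrames]` (FD is a
#'   backward difference, undefined at the first frame).
#' @param spikeAmpMm spike step amplitude, millimetres.
#' @param driftMmPerFrame linear drift slope, millimetres per frame.
#' @param jitterSd SD of white positional jitter in mm (rotational jitter is
#'   scaled by 1/50 so its framewise-displacement contribution matches the
#'   translations under a 50 mm head radius), default 0.
#' @param seed integer seed (used only when `jitterSd > 0`).
#' @return numeric `nFrames` x 6 matrix, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
makeMotionTrace <- function(nFrames, spikeFrames = integer(0),
                            spikeAmpMm = 0.5, driftMmPerFrame = 0,
                            jitterSd = 0, seed = 1L) {
  stopIfNot(nFrames >= 2, "nFrames must be >= 2")
  if (length(spikeFrames) &&
      (any(spikeFrames < 2) || any(spikeFrames > nFrames)))
    stop("spike frames must lie in [2, nFrames]: FD is undefined at the first frame",
         call. = FALSE)
  m <- matrix(0, nFrames, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  m[, 1] <- driftMmPerFrame * (seq_len(nFrames) - 1)
  for (f in spikeFrames) m[f:nFrames, 1] <- m[f:nFrames, 1] + spikeAmpMm
  if (jitterSd > 0) {
    jit <- withSeed(seed, matrix(rnorm(nFrames * 6, sd = jitterSd),
                                 nFrames, 6))
    jit[, 4:6] <- jit[, 4:6] / 50
    m <- m + jit
  }
  m
}

#' Network-structured inter-regional correlation matrix
#'
#' Block-diagonal structure: regions are grouped into consecutive networks
#' of `blockSize` regions with common within-network correlation `rho` and
#' zero between-network correlation. This mimics resting-state functional
#' networks, which are coherent internally but not brain-wide (a globally
#' exchangeable structure would make the neuronal component leak heavily
#' into the whole-brain mean, which real neuronal activity does not).
#' `blockSize = nRegions` gives the exchangeable special case.
#'
#' @param nRegions number of regions.
#' @param rho within-network correlation in `[0, 1]`.
#' @param blockSize regions per network, default 7.
#' @return nRegions x nRegions correlation matrix.
#' @export
makeNetworkCorr <- function(nRegions, rho = 0.3, blockSize = 7L) {
  stopIfNot(rho >= 0 && rho <= 1, "rho must lie in [0, 1]")
  block <- ceiling(seq_len(nRegions) / blockSize)
  C <- outer(block, block, "==") * rho
  diag(C) <- 1
  C
}

#' Ground-truth parameters for one synthetic subject
#'
#' Regional CVR gains are dimensionless fractions of baseline per unit
#' surrogate. White matter is far less vascularized than gray matter
#' (roughly 70-75% less vasculature), so the default gray:white gain ratio
#' is 3.5, configurable.
#'
#' @param nRegions number of gray-matter parcels.
#' @param wmGain white-matter CVR gain (fraction of baseline per unit
#'   surrogate), default 0.004.
#' @param gmWmRatio mean gray:white gain ratio, default 3.5.
#' @param regionalSd lognormal SD of the regional gain profile, default 0.2.
#' @param networkCorr region x region neuronal correlation matrix
#'   (symmetric, unit diagonal, PSD); default exchangeable 0.25.
#' @param spikeFrames,spikeAmpMm,driftMmPerFrame,jitterSd motion
#'   specification, passed to [makeMotionTrace()]; the default 0.01 mm
#'   jitter gives realistic subject-varying mean FD well below the
#'   censoring threshold.
#' @param seed integer seed for the regional profile draw.
#' @return list of class `subjectTruth` with elements `regionalCvrGain`,
#'   `wmCvrGain`, `networkCorr`, `motionSpec`.
#' @export
subjectTruth <- function(nRegions = 91L, wmGain = 0.004, gmWmRatio = 3.5,
                         regionalSd = 0.2, networkCorr = NULL,
                         spikeFrames = integer(0), spikeAmpMm = 0.5,
                         driftMmPerFrame = 0, jitterSd = 0.01, seed = 1L) {
  stopIfNot(wmGain >= 0, "gains must be >= 0")
  if (is.null(networkCorr)) networkCorr <- makeNetworkCorr(nRegions)
  profile <- withSeed(seed, exp(rnorm(nRegions, 0, regionalSd)))
  gains <- wmGain * gmWmRatio * profile
  truth <- list(regionalCvrGain = gains, wmCvrGain = wmGain,
                networkCorr = networkCorr,
                motionSpec = list(spikeFrames = as.integer(spikeFrames),
                                  spikeAmpMm = spikeAmpMm,
                                  driftMmPerFrame = driftMmPerFrame,
                                  jitterSd = jitterSd))
  validateSubjectTruth(truth)
  structure(truth, class = "subjectTruth")
}

validateSubjectTruth <- function(truth) {
  stopIfNot(all(truth$regionalCvrGain >= 0) && truth$wmCvrGain >= 0,
            "all gains must be >= 0")
  stopIfNot(mean(truth$regionalCvrGain) > truth$wmCvrGain,
            "mean gray-matter gain must exceed the white-matter gain")
  C <- truth$networkCorr
  stopIfNot(isSymmetric(unname(C)) && all(abs(diag(C) - 1) < 1e-12),
            "networkCorr must be symmetric with unit diagonal")
  stopIfNot(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) >
              -1e-8, "networkCorr must be positive semi-definite")
  invisible(TRUE)
}

# Band-limited correlated neuronal signals: MVN columns via Cholesky,
# identical zero-phase filtering per column (which preserves the target
# correlation in expectation), then per-column standardization.
makeNeuronalSignals <- function(nFrames, trS, networkCorr,
                                bandHz = c(0.008, 0.1), seed = 1L) {
  R <- ncol(networkCorr)
  Z <- withSeed(seed, matrix(rnorm(nFrames * R), nFrames, R))
  ev <- eigen(networkCorr, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), R) %*% t(ev$vectors)
  X <- Z %*% L
  hi <- min(bandHz[2], 0.98 / (2 * trS))
  X <- apply(X, 2, butterBandpass, loHz = bandHz[1], hiHz = hi, trS = trS)
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  sweep(X, 2, sds, "/")
}

#' Synthesize one subject's 4D BOLD run from ground truth
#'
#' Signal model (multiplicative on baseline, percent-signal convention):
#' gray-matter voxel in parcel r follows
#' `baseline * (1 + gain_r * s_t + neuronalAmp * n_{r,t} + a_t * u_v) + eps`,
#' where `s` is the vasodilatory surrogate, `n_r` are band-limited
#' (0.008-0.1 Hz) neuronal signals with the truth's inter-regional
#' correlation, `a_t` is a motion artifact active only at spike frames
#' (amplitude `artifactGainPerMm` per mm of spike, voxel pattern `u_v`), and
#' `eps` is i.i.d. noise with SD `noiseSd`. White matter uses the
#' white-matter gain and no neuronal component; CSF carries baseline and
#' noise only.
#'
#' @param truth a [subjectTruth()] list.
#' @param acq an [acquisitionConfig()].
#' @param surrogate numeric surrogate series of length `nFrames`.
#' @param seed integer seed.
#' @param geometry optional list(masks, atlas) from [phantomGeometry()];
#'   built on the fly (91 parcels or `length(truth$regionalCvrGain)`) if
#'   missing.
#' @param neuronalAmp fractional amplitude of the neuronal component,
#'   default 0.01 (1% signal change).
#' @param artifactGainPerMm fractional signal disturbance per millimetre of
#'   motion spike, default 0.03.
#' @return list of class `syntheticSubject`: `bold` ([BoldRun-class]),
#'   `masks`, `atlas`, `motion` (frames x 6 matrix), `truth`, `phenotype`.
#' @export
makeSubject <- function(truth, acq = acquisitionConfig(),
                        surrogate = NULL, seed = 1L, geometry = NULL,
                        neuronalAmp = 0.01, artifactGainPerMm = 0.03) {
  nR <- length(truth$regionalCvrGain)
  if (is.null(geometry)) geometry <- phantomGeometry(acq$gridShape, nR)
  masks <- geometry$masks; atlas <- geometry$atlas
  stopIfNot(identical(dim(gmMask(masks)), acq$gridShape),
            "geometry grid does not match the acquisition grid")
  stopIfNot(nRegions(atlas) == nR,
            "atlas region count does not match truth$regionalCvrGain length")
  seeds <- childSeeds(seed, 4)
  if (is.null(surrogate))
    surrogate <- makeCo2Surrogate(acq$nFrames, acq$trS, seed = seeds[1])
  stopIfNot(length(surrogate) == acq$nFrames,
            "surrogate length must equal nFrames")

  grid <- acq$gridShape; nT <- acq$nFrames
  V <- prod(grid)
  gm <- as.vector(gmMask(masks)); wm <- as.vector(wmMask(masks))
  labs <- as.vector(atlasVolume(atlas))

  gainVec <- numeric(V)
  gainVec[wm] <- truth$wmCvrGain
  gainVec[gm] <- truth$regionalCvrGain[labs[gm]]

  Y <- matrix(1, nT, V)                      # frames x voxels, relative units
  Y <- Y + tcrossprod(surrogate, gainVec)
  if (neuronalAmp > 0) {
    N <- makeNeuronalSignals(nT, acq$trS, truth$networkCorr, seed = seeds[2])
    Y[, gm] <- Y[, gm] + neuronalAmp * N[, labs[gm]]
  }
  ms <- truth$motionSpec
  motion <- makeMotionTrace(nT, ms$spikeFrames, ms$spikeAmpMm,
                            ms$driftMmPerFrame,
                            jitterSd = if (is.null(ms$jitterSd)) 0
                                       else ms$jitterSd,
                            seed = seeds[3])
  if (length(ms$spikeFrames) && artifactGainPerMm > 0) {
    # each movement event disturbs the image with its own spatial pattern,
    # so motion regressors alone cannot absorb all of them
    U <- withSeed(seeds[4], matrix(rnorm(V * length(ms$spikeFrames)),
                                   length(ms$spikeFrames), V))
    for (k in seq_along(ms$spikeFrames))
      Y[ms$spikeFrames[k], ] <- Y[ms$spikeFrames[k], ] +
        ms$spikeAmpMm * artifactGainPerMm * U[k, ]
  }
  Y <- Y * acq$baselineIntensity
  if (acq$noiseSd > 0)
    Y <- Y + withSeed(seeds[4] + 1, matrix(rnorm(nT * V, sd = acq$noiseSd),
                                           nT, V))
  bold <- BoldRun(voxelsTo4d(Y, grid), trS = acq$trS,
                  voxelSizeMm = acq$voxelSizeMm, mask = brainMask(masks))
  structure(list(bold = bold, masks = masks, atlas = atlas, motion = motion,
                 truth = truth, phenotype = NULL),
            class = "syntheticSubject")
}

#' Cohort configuration for the multi-site synthetic generator
#'
#' Defines cell sizes (diagnosis x sex), site structure, the base regional
#' rCVR profile, injected group effects under the same +/-1 effect coding
#' the downstream models use (diagnosis: ASD = -1, NA = +1; sex: M = -1,
#' F = +1), site batch effects, and subject noise.
#'
#' The subject-level regional noise SD defaults to 0.75 rCVR units,
#' calibrated analytically so that the reference design (cells
#' 79/16/125/74) detects an interaction coefficient of 0.19 with roughly
#' 90% power at alpha = 0.05.
#'
#' @param cells named integer vector of cell sizes, names `MA`, `FA`, `MN`,
#'   `FN` (male/female x autistic/non-autistic).
#' @param nSites number of acquisition sites (>= 1); subjects are dealt to
#'   sites round-robin within cells so sites stay balanced.
#' @param nRegions number of atlas regions.
#' @param baseRcvr mean regional rCVR level, default 3.5 (gray:white ratio).
#' @param baseProfileSd SD of the fixed regional profile around `baseRcvr`.
#' @param groupEffects `nRegions` x 3 matrix (columns `diagnosis`, `sex`,
#'   `interaction`) of per-region coefficients on the coded design, or NULL
#'   for no effects.
#' @param siteAdditiveSd SD of per-site, per-region additive offsets.
#' @param siteMultiplicativeSdLog log-SD of per-site, per-region positive
#'   scale factors applied to the subject noise (the location/scale batch
#'   model the harmonization stage assumes).
#' @param subjectSd subject-level regional noise SD (rCVR units).
#' @param ageRange age range in years, sampled uniformly.
#' @return list of class `cohortConfig`.
#' @export
cohortConfig <- function(cells = c(MA = 10L, FA = 10L, MN = 10L, FN = 10L),
                         nSites = 2L, nRegions = 91L, baseRcvr = 3.5,
                         baseProfileSd = 0.3, groupEffects = NULL,
                         siteAdditiveSd = 0.3,
                         siteMultiplicativeSdLog = 0.15,
                         subjectSd = 0.75, ageRange = c(9, 12)) {
  stopIfNot(all(c("MA", "FA", "MN", "FN") %in% names(cells)),
            "cells must name MA, FA, MN, FN")
  stopIfNot(all(cells >= 1), "each requested cell needs >= 1 subject")
  stopIfNot(nSites >= 1, "need >= 1 site")
  if (!is.null(groupEffects)) {
    stopIfNot(is.matrix(groupEffects) && nrow(groupEffects) == nRegions &&
                ncol(groupEffects) == 3,
              "groupEffects must be an nRegions x 3 matrix")
    stopIfNot(all(is.finite(groupEffects)), "groupEffects must be finite")
  }
  structure(list(cells = cells, nSites = as.integer(nSites),
                 nRegions = as.integer(nRegions), baseRcvr = baseRcvr,
                 baseProfileSd = baseProfileSd, groupEffects = groupEffects,
                 siteAdditiveSd = siteAdditiveSd,
                 siteMultiplicativeSdLog = siteMultiplicativeSdLog,
                 subjectSd = subjectSd, ageRange = ageRange),
            class = "cohortConfig")
}

#' Reference cohort configuration
#'
#' Cell sizes 79 autistic males, 16 autistic females, 125 non-autistic
#' males, 74 non-autistic females (294 children across 8 sites). With
#' `effectPattern = "interaction"` two regions receive a female-specific
#' diagnostic elevation (diagnosis and interaction coefficients both
#' negative under ASD = -1 / F = +1 coding, so autistic females sit higher
#' while males show no diagnostic difference), with design magnitudes 0.19
#' and 0.14.
#'
#' @param effectPattern `"none"` or `"interaction"`.
#' @param effectRegions integer vector of 2 region indices carrying the
#'   pattern.
#' @param ... further arguments to [cohortConfig()].
#' @return list of class `cohortConfig`.
#' @export
referenceCohortConfig <- function(effectPattern = c("none", "interaction"),
                              effectRegions = c(1L, 2L), ...) {
  effectPattern <- match.arg(effectPattern)
  nRegions <- list(...)$nRegions
  if (is.null(nRegions)) nRegions <- 91L
  ge <- NULL
  if (effectPattern == "interaction") {
    stopIfNot(all(effectRegions >= 1 & effectRegions <= nRegions),
              "effect pattern references an unknown region label")
    ge <- matrix(0, nRegions, 3,
                 dimnames = list(NULL, c("diagnosis", "sex", "interaction")))
    mags <- c(0.19, 0.14)
    for (k in seq_along(effectRegions)) {
      ge[effectRegions[k], "diagnosis"] <- -mags[k]
      ge[effectRegions[k], "interaction"] <- -mags[k]
    }
  }
  cohortConfig(cells = c(MA = 79L, FA = 16L, MN = 125L, FN = 74L),
               nSites = 8L, groupEffects = ge, ...)
}

#' Generate a multi-site synthetic cohort with ground truth
#'
#' Subject-level regional rCVR features are built as
#' `base_r + b_dx * x + b_sex * y + b_int * x * y + site_add + site_mult * eps`
#' under +/-1 effect coding, together with a phenotype table and a complete
#' `cohortTruth` manifest. Site effects are injected on the regional summary
#' features (the quantities the harmonization stage operates on). With
#' `images = TRUE`, per-subject 4D BOLD runs are also synthesized whose
#' gray-matter gains encode the biological (site-free) feature values, so
#' the voxel-level pipeline can recover them.
#'
#' @param config a [cohortConfig()].
#' @param seed integer master seed.
#' @param images synthesize per-subject images too (keep cohorts small).
#' @param acq [acquisitionConfig()] used when `images = TRUE`.
#' @return list of class `syntheticCohort`: `features` (regions x subjects
#'   matrix, site effects applied), `phenotypes` (data.frame), `truth`
#'   (`cohortTruth` manifest), and `subjects` (list, only when
#'   `images = TRUE`).
#' @export
makeCohort <- function(config = cohortConfig(), seed = 1L, images = FALSE,
                       acq = acquisitionConfig()) {
  seeds <- childSeeds(seed, 6)
  cells <- config$cells
  nSub <- sum(cells)
  nR <- config$nRegions
  diagnosis <- rep(c("ASD", "ASD", "NA", "NA"), cells[c("MA", "FA", "MN", "FN")])
  sex <- rep(c("M", "F", "M", "F"), cells[c("MA", "FA", "MN", "FN")])
  site <- unlist(lapply(cells[c("MA", "FA", "MN", "FN")], function(m)
    rep_len(seq_len(config$nSites), m)), use.names = FALSE)
  x <- ifelse(diagnosis == "ASD", -1, 1)
  y <- ifelse(sex == "M", -1, 1)

  base <- withSeed(seeds[1],
                   config$baseRcvr + rnorm(nR, 0, config$baseProfileSd))
  ge <- config$groupEffects
  if (is.null(ge)) ge <- matrix(0, nR, 3)
  bio <- base + ge[, 1, drop = TRUE] %o% x + ge[, 2, drop = TRUE] %o% y +
    ge[, 3, drop = TRUE] %o% (x * y)
  eps <- withSeed(seeds[2], matrix(rnorm(nR * nSub, 0, config$subjectSd),
                                   nR, nSub))
  siteAdd <- withSeed(seeds[3],
                      matrix(rnorm(nR * config$nSites, 0,
                                   config$siteAdditiveSd), nR, config$nSites))
  siteMult <- withSeed(seeds[4],
                       matrix(exp(rnorm(nR * config$nSites, 0,
                                        config$siteMultiplicativeSdLog)),
                              nR, config$nSites))
  if (config$nSites == 1L) { siteAdd[] <- 0; siteMult[] <- 1 }
  feats <- bio + eps * siteMult[, site] + siteAdd[, site]
  rownames(feats) <- sprintf("region_%03d", seq_len(nR))

  ids <- sprintf("sub-%04d", seq_len(nSub))
  colnames(feats) <- ids
  pheno <- data.frame(
    subject_id = ids,
    site = sprintf("site_%02d", site),
    diagnosis = diagnosis, sex = sex,
    age = withSeed(seeds[5], runif(nSub, config$ageRange[1],
                                   config$ageRange[2])),
    mean_fd = withSeed(seeds[6], pmax(0.02, rnorm(nSub, 0.12, 0.05))),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    baseRcvr = base, groupEffects = ge,
    bioFeatures = bio + eps,
    siteAdditive = siteAdd, siteMultiplicative = siteMult,
    siteAssignment = site, rngSeed = as.integer(seed),
    subjectSd = config$subjectSd), class = "cohortTruth")

  out <- list(features = feats, phenotypes = pheno, truth = truth)
  if (images) {
    wmGain <- 0.004
    geom <- phantomGeometry(acq$gridShape, nR)
    subjSeeds <- childSeeds(seeds[2] + 17, nSub)
    out$subjects <- lapply(seq_len(nSub), function(s) {
      tr <- subjectTruth(nRegions = nR, wmGain = wmGain, seed = subjSeeds[s])
      tr$regionalCvrGain <- pmax(wmGain * truth$bioFeatures[, s], 0)
      subj <- makeSubject(tr, acq, seed = subjSeeds[s], geometry = geom)
      subj$phenotype <- pheno[s, , drop = FALSE]
      subj
    })
  }
  structure(out, class = "syntheticCohort")
}
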