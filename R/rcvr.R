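#' Whole-brain mean signal
#'
#' @param bold a [BoldRun-class].
#' @param mask logical 3D mask (default: the run's brain mask; for the CO2
#'   surrogate this should be GM + WM + CSF).
#' @return numeric per-frame mean over mask voxels.
#' @export
globalSignal <- function(bold, mask = NULL) {
  if (is.null(mask)) mask <- brainMask(bold)
  stopIfNot(any(mask), "mask is empty")
  Y <- framesByVoxels(boldData(bold))
  rowMeans(Y[, as.vector(mask), drop = FALSE])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Linear detrend, then a 4th-order Butterworth band-pass applied
#' forward-backward (zero phase); output is demeaned.
#'
#' @param ts numeric time series.
#' @param loHz,hiHz pass band edges in Hz, `0 < lo < hi < Nyquist`.
#' @param trS repetition time, seconds.
#' @return filtered, demeaned series of the same length.
#' @export
bandpass <- function(ts, loHz, hiHz, trS) {
  butterBandpass(ts, loHz, hiHz, trS)
}

#' Extract the band-limited CO2 surrogate from a preprocessed run
#'
#' The whole-brain (GM + WM + CSF) mean BOLD signal, band-limited to the
#' respiratory volume-variation band (0.02-0.04 Hz by default), demeaned.
#' Computed on the fully preprocessed data (after nuisance regression and
#' smoothing).
#'
#' @param bold a preprocessed [BoldRun-class].
#' @param masks a [SegmentationMasks-class] (surrogate mask = union), or
#'   NULL to use the run's brain mask.
#' @param bandHz pass band, default `c(0.02, 0.04)` Hz.
#' @return a [Co2Surrogate-class].
#' @export
extractCo2Surrogate <- function(bold, masks = NULL,
                                bandHz = c(0.02, 0.04)) {
  mask <- if (is.null(masks)) brainMask(bold) else brainMask(masks)
  gs <- globalSignal(bold, mask)
  flt <- bandpass(gs, bandHz[1], bandHz[2], trS(bold))
  new("Co2Surrogate", series = flt - mean(flt), bandHz = bandHz,
      source = if (is.null(masks)) "brain_mask" else "gm+wm+csf")
}

#' Voxel-wise CVR slope map
#'
#' Per voxel, the ordinary least-squares slope of the (preprocessed) voxel
#' series on (intercept, surrogate): the local BOLD change per unit change
#' of the CO2 surrogate.
#'
#' @param bold a [BoldRun-class].
#' @param surrogate a [Co2Surrogate-class] or numeric series.
#' @return 3D numeric array of slopes.
#' @export
cvrBetaMap <- function(bold, surrogate) {
  s <- if (is(surrogate, "Co2Surrogate")) surrogateSeries(surrogate)
       else surrogate
  stopIfNot(length(s) == nFrames(bold),
            "surrogate length must equal the frame count")
  sc <- s - mean(s)
  ss <- sum(sc^2)
  stopIfNot(ss > 0, "surrogate has zero variance")
  Y <- framesByVoxels(boldData(bold))
  beta <- as.vector(crossprod(Y, sc)) / ss
  array(beta, gridDim(bold))
}

#' Inverse-tSNR voxel exclusion
#'
#' Inverse temporal signal-to-noise ratio (temporal SD / temporal mean,
#' computed on data whose voxel means were retained) flags large vessels,
#' CSF and artifact. Voxels strictly above the given percentile
#' (linear-interpolation percentile over in-mask voxels) are excluded;
#' in-mask voxels with non-positive temporal mean are auto-excluded with a
#' warning.
#'
#' @param bold a [BoldRun-class] with voxel means retained.
#' @param mask logical 3D mask over which the percentile is taken.
#' @param percentile exclusion percentile, default 98.
#' @return logical 3D array, TRUE = excluded.
#' @export
itsnrExclusion <- function(bold, mask = NULL, percentile = 98) {
  if (is.null(mask)) mask <- brainMask(bold)
  Y <- framesByVoxels(boldData(bold))
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, sd)
  inMask <- as.vector(mask)
  badMean <- inMask & mu <= 0
  if (any(badMean))
    warning(sprintf("%d in-mask voxels with non-positive temporal mean auto-excluded",
                    sum(badMean)))
  itsnr <- rep(NA_real_, length(mu))
  ok <- inMask & mu > 0
  itsnr[ok] <- sdv[ok] / mu[ok]
  thr <- quantile(itsnr[ok], percentile / 100, type = 7, names = FALSE)
  excl <- badMean
  excl[ok] <- itsnr[ok] > thr
  array(excl, gridDim(bold))
}

#' Normalize a CVR slope map to relative CVR
#'
#' The reference is the mean slope over non-excluded reference voxels:
#' white matter (`mode = "white_matter"`, the default) or the whole brain
#' (`mode = "global"`, the supplementary variant). rCVR = beta / reference.
#'
#' @param beta 3D slope array from [cvrBetaMap()].
#' @param masks a [SegmentationMasks-class].
#' @param excluded logical 3D exclusion array (default: none).
#' @param mode `"white_matter"` or `"global"`.
#' @return a [CvrMap-class].
#' @export
normalizeCvr <- function(beta, masks, excluded = NULL,
                         mode = c("white_matter", "global")) {
  mode <- match.arg(mode)
  if (is.null(excluded)) excluded <- array(FALSE, dim(beta))
  refMask <- if (mode == "white_matter") wmMask(masks) else brainMask(masks)
  refVox <- refMask & !excluded
  stopIfNot(sum(refVox) >= 10,
            "reference region has fewer than 10 non-excluded voxels")
  ref <- mean(beta[refVox])
  betaSd <- sd(beta[brainMask(masks)])
  if (!is.finite(ref) || ref <= 1e-6 * betaSd)
    stop("degenerate reference: mean reference beta is not positive ",
         "relative to the in-mask beta spread (no vascular signal present)",
         call. = FALSE)
  rcvr <- beta / ref
  rcvr[excluded] <- NA_real_
  new("CvrMap", beta = beta, rcvr = rcvr,
      excluded = asLogicalArray(excluded),
      normalizationMode = mode, referenceBeta = ref)
}

#' Average a voxel map within atlas regions
#'
#' Per region, the mean over member voxels that are not excluded; regions
#' with no surviving voxels are returned as NA (missing), never 0.
#'
#' @param volume 3D numeric array (e.g. an rCVR map).
#' @param atlas an [AtlasLabels-class] on the same grid.
#' @param excluded optional logical 3D exclusion array.
#' @return named numeric vector, one value per lookup region.
#' @export
regionalAverage <- function(volume, atlas, excluded = NULL) {
  stopIfNot(identical(dim(volume), dim(atlasVolume(atlas))),
            "atlas grid does not match the volume grid")
  if (is.null(excluded)) excluded <- array(FALSE, dim(volume))
  labs <- atlasVolume(atlas)
  lk <- atlasLookup(atlas)
  use <- labs != 0 & !excluded
  sums <- tapply(volume[use], labs[use], mean)
  out <- setNames(rep(NA_real_, nrow(lk)), lk$name)
  hit <- match(as.integer(names(sums)), lk$label)
  out[hit] <- as.numeric(sums)
  out
}

#' Motion-QC association between rCVR and mean framewise displacement
#'
#' Pearson correlation (with p-value) between subject-level gray-matter
#' mean rCVR and mean FD, plus per-region correlations with mean FD.
#' Within-subject normalization makes rCVR robust to motion, so on clean
#' data these associations should be null.
#'
#' @param regionalRcvr subjects x regions matrix.
#' @param gmMeanRcvr per-subject gray-matter mean rCVR.
#' @param meanFd per-subject mean FD (mm).
#' @return list: `global` (data.frame r, p, n, flag) and `regional`
#'   (data.frame region, r, p).
#' @export
motionQc <- function(regionalRcvr, gmMeanRcvr, meanFd) {
  n <- length(meanFd)
  stopIfNot(n >= 3, "need >= 3 subjects for a correlation p-value")
  flag <- if (n < 10) "low_power" else ""
  safeCor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(a, b)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  gl <- safeCor(gmMeanRcvr, meanFd)
  if (is.na(gl["r"])) flag <- paste(flag, "undefined_correlation")
  reg <- t(apply(regionalRcvr, 2, safeCor, b = meanFd))
  list(global = data.frame(r = gl["r"], p = gl["p"], n = n,
                           flag = trimws(flag), row.names = NULL),
       regional = data.frame(region = colnames(regionalRcvr),
                             r = reg[, 1], p = reg[, 2], row.names = NULL))
}

#' Per-subject rCVR computation from a preprocessed run
#'
#' Extracts the CO2 surrogate from the fully preprocessed data, fits the
#' voxel-wise slope map, applies inverse-tSNR exclusion, normalizes to the
#' reference tissue, and averages within atlas regions.
#'
#' @param bold a preprocessed [BoldRun-class] (voxel means retained).
#' @param masks a [SegmentationMasks-class].
#' @param atlas an [AtlasLabels-class].
#' @param config a [pipelineConfig()].
#' @return list: `cvrMap` ([CvrMap-class]), `surrogate`
#'   ([Co2Surrogate-class]), `regional` (named per-region rCVR vector),
#'   `gmMean` (mean rCVR over non-excluded GM voxels).
#' @export
computeRcvr <- function(bold, masks, atlas, config = pipelineConfig()) {
  surr <- extractCo2Surrogate(bold, masks, config$bandCvrHz)
  beta <- cvrBetaMap(bold, surr)
  excl <- if (config$itsnrPercentile >= 100)
    array(FALSE, gridDim(bold))
  else itsnrExclusion(bold, brainMask(masks), config$itsnrPercentile)
  cvr <- normalizeCvr(beta, masks, excl, config$normalizationMode)
  regional <- regionalAverage(rcvrVolume(cvr), atlas, excludedMask(cvr))
  gmOk <- gmMask(masks) & !excludedMask(cvr)
  list(cvrMap = cvr, surrogate = surr, regional = regional,
       gmMean = mean(rcvrVolume(cvr)[gmOk]))
}
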