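#' Expand 6 rigid-body parameters to the 18-parameter motion set
#'
#' Columns are ordered as the 6 base parameters, their 6 backward-difference
#' temporal derivatives (first row 0), and the 6 element-wise squares of the
#' base parameters. The count of 18 forces reading "square of motion" as
#' squares of the base parameters, not of the derivatives. Regressors are
#' used as-is (not demeaned before squaring); the design intercept absorbs
#' offsets.
#'
#' @param motion frames x 6 numeric matrix (3 translations mm,
#'   3 rotations rad).
#' @return frames x 18 numeric matrix.
#' @export
expandMotion <- function(motion) {
  motion <- as.matrix(motion)
  stopIfNot(nrow(motion) >= 2, "need >= 2 frames")
  stopIfNot(ncol(motion) == 6, "motion trace must have 6 columns")
  stopIfNot(all(is.finite(motion)), "motion trace contains non-finite values")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2)
  colnames(out) <- c(paste0("mot_", 1:6), paste0("dmot_", 1:6),
                     paste0("mot2_", 1:6))
  out
}

#' Framewise displacement from a rigid-body motion trace
#'
#' `FD_t = sum |delta translation| + r * sum |delta rotation|` with the
#' rotations converted to arc length on a sphere of radius
#' `headRadiusMm` (default 50 mm, the standard convention); `FD_1 = 0`.
#'
#' @param motion frames x 6 matrix (translations mm, rotations rad).
#' @param headRadiusMm head radius for rotation-to-displacement conversion.
#' @return numeric FD series in millimetres, first element 0.
#' @export
computeFD <- function(motion, headRadiusMm = 50) {
  motion <- as.matrix(motion)
  stopIfNot(nrow(motion) >= 2, "FD needs >= 2 frames")
  stopIfNot(headRadiusMm > 0, "headRadiusMm must be positive")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Spike (censoring) regressors from a framewise-displacement series
#'
#' One one-hot column per frame with FD strictly greater than the threshold
#' ("greater than" is a strict inequality: FD exactly at the threshold is
#' kept).
#'
#' @param fd numeric FD series, millimetres.
#' @param thresholdMm censoring threshold, default 0.25 mm.
#' @param trS repetition time in seconds (for the remaining-duration field).
#' @return list with `spikes` (frames x nCensored one-hot matrix, 0 columns
#'   when nothing is censored) and `censor` ([CensorInfo-class]).
#' @export
censorDesign <- function(fd, thresholdMm = 0.25, trS = 2.5) {
  stopIfNot(thresholdMm > 0, "thresholdMm must be positive")
  n <- length(fd)
  bad <- which(fd > thresholdMm)
  spikes <- matrix(0, n, length(bad))
  if (length(bad)) {
    spikes[cbind(bad, seq_along(bad))] <- 1
    colnames(spikes) <- sprintf("spike_%03d", bad)
  }
  keep <- rep(TRUE, n); keep[bad] <- FALSE
  censor <- new("CensorInfo", fdSeries = fd, keepMask = keep,
                censoredFraction = 1 - mean(keep),
                remainingSeconds = sum(keep) * trS,
                thresholdMm = thresholdMm)
  list(spikes = spikes, censor = censor)
}

#' Participant inclusion decision from censoring results
#'
#' Include iff fewer than `maxCensoredFraction` of frames are censored AND
#' at least `minRemainingMinutes` of data remain after censoring. Both
#' reasons are reported on exclusion.
#'
#' @param censor a [CensorInfo-class].
#' @param maxCensoredFraction inclusion bound on the censored fraction,
#'   default 0.25 (strict: the fraction must be below this).
#' @param minRemainingMinutes minimum retained duration, default 4 minutes.
#' @return list with `include` (logical) and `reasons` (character vector of
#'   failed rules, empty when included).
#' @export
checkInclusion <- function(censor, maxCensoredFraction = 0.25,
                           minRemainingMinutes = 4) {
  stopIfNot(maxCensoredFraction > 0 && maxCensoredFraction < 1,
            "maxCensoredFraction must lie in (0, 1)")
  reasons <- character(0)
  if (!(censoredFraction(censor) < maxCensoredFraction))
    reasons <- c(reasons,
                 sprintf("censored fraction %.3f >= %.3f",
                         censoredFraction(censor), maxCensoredFraction))
  if (!(remainingSeconds(censor) >= 60 * minRemainingMinutes))
    reasons <- c(reasons,
                 sprintf("remaining data %.1f s < %.1f s",
                         remainingSeconds(censor), 60 * minRemainingMinutes))
  list(include = length(reasons) == 0L, reasons = reasons)
}

#' Assemble the per-frame nuisance design
#'
#' Intercept, linear trend, the 18 expanded motion parameters, one spike
#' column per censored frame, and optionally white-matter and CSF mean
#' series (used for the functional-connectivity variant). Exactly collinear
#' columns (zero columns, duplicates) are dropped with a message; the
#' returned design is full column rank.
#'
#' @param motion frames x 6 motion trace.
#' @param spikes frames x k one-hot spike matrix (possibly 0 columns).
#' @param wmSeries,csfSeries optional per-frame nuisance series.
#' @return numeric design matrix with column labels and attribute
#'   `"dropped"` naming any pruned columns.
#' @export
nuisanceDesign <- function(motion, spikes = NULL, wmSeries = NULL,
                           csfSeries = NULL) {
  n <- nrow(as.matrix(motion))
  X <- cbind(intercept = rep(1, n),
             trend = seq_len(n) - (n + 1) / 2,
             expandMotion(motion))
  if (!is.null(spikes) && ncol(spikes) > 0) X <- cbind(X, spikes)
  if (!is.null(wmSeries)) X <- cbind(X, wm_mean = wmSeries)
  if (!is.null(csfSeries)) X <- cbind(X, csf_mean = csfSeries)
  pruneCollinear(X)
}

# Drop exactly-collinear columns (keeping the earliest), message which.
pruneCollinear <- function(X) {
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    message("dropping exactly-collinear nuisance columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

#' Regress nuisance signals out of every voxel series
#'
#' Each voxel series is replaced by its least-squares residual against the
#' design, plus its own temporal mean (the mean is retained so temporal SNR
#' stays defined downstream). Spike columns in the design zero the censored
#' frames' influence, which is the censoring-by-regression convention.
#'
#' @param bold a [BoldRun-class].
#' @param design frames x p nuisance design (see [nuisanceDesign()]).
#' @return a [BoldRun-class] with residualized data (means retained).
#' @export
nuisanceRegress <- function(bold, design) {
  Y <- framesByVoxels(boldData(bold))
  stopIfNot(nrow(design) == nrow(Y),
            "design row count must equal the frame count")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[setdiff(seq_len(ncol(design)),
                                    qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qrX, Y)
  res <- sweep(res, 2, colMeans(Y), "+")
  BoldRun(voxelsTo4d(res, gridDim(bold)), trS = trS(bold),
          voxelSizeMm = voxelSizeMm(bold), mask = brainMask(bold))
}

#' Gaussian spatial smoothing with mask renormalization
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma_mm = fwhm / (2 * sqrt(2 * log(2)))`, renormalized by the smoothed
#' mask so a spatially constant image is unchanged inside the mask. Voxels
#' outside the mask are passed through untouched.
#'
#' @param bold a [BoldRun-class].
#' @param fwhmMm kernel full-width-half-max in millimetres (0 = identity;
#'   default 8 mm).
#' @param mask logical 3D mask; defaults to the run's brain mask.
#' @return a smoothed [BoldRun-class].
#' @export
smoothGaussian <- function(bold, fwhmMm = 8, mask = NULL) {
  stopIfNot(fwhmMm >= 0, "fwhmMm must be >= 0")
  if (fwhmMm == 0) return(bold)
  if (is.null(mask)) mask <- brainMask(bold)
  if (fwhmMm < voxelSizeMm(bold))
    warning("smoothing FWHM is below the voxel size; proceeding")
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm(bold)
  grid <- gridDim(bold)
  Kx <- gaussKernelMatrix(grid[1], sigmaVox)
  Ky <- gaussKernelMatrix(grid[2], sigmaVox)
  Kz <- gaussKernelMatrix(grid[3], sigmaVox)
  m <- array(as.numeric(mask), grid)
  W <- smooth3d(m, Kx, Ky, Kz)
  arr <- boldData(bold)
  out <- arr
  inside <- which(mask)
  for (t in seq_len(nFrames(bold))) {
    vol <- arr[, , , t]
    sm <- smooth3d(vol * m, Kx, Ky, Kz)
    frame <- vol
    frame[inside] <- sm[inside] / W[inside]
    out[, , , t] <- frame
  }
  BoldRun(out, trS = trS(bold), voxelSizeMm = voxelSizeMm(bold),
          mask = brainMask(bold))
}

#' Run the full per-subject preprocessing chain
#'
#' Motion expansion, FD computation, spike-regressor construction, nuisance
#' regression (intercept + trend + 18 motion parameters + spikes), then
#' Gaussian smoothing, in that order. Mean FD is computed over all frames,
#' pre-censoring, as the subject-level motion covariate.
#'
#' @param bold a [BoldRun-class].
#' @param motion frames x 6 motion trace.
#' @param config a [pipelineConfig()] (thresholds, FWHM, head radius).
#' @param wmSeries,csfSeries optional nuisance series (FC variant).
#' @return list: `bold` (preprocessed run), `censor` ([CensorInfo-class]),
#'   `meanFd`, `inclusion` (from [checkInclusion()]), `design`.
#' @export
preprocessBold <- function(bold, motion, config = pipelineConfig(),
                           wmSeries = NULL, csfSeries = NULL) {
  fd <- computeFD(motion, config$headRadiusMm)
  cd <- censorDesign(fd, config$fdThresholdMm, trS(bold))
  design <- nuisanceDesign(motion, cd$spikes, wmSeries, csfSeries)
  cleaned <- nuisanceRegress(bold, design)
  smoothed <- smoothGaussian(cleaned, config$smoothingFwhmMm)
  list(bold = smoothed, censor = cd$censor, meanFd = mean(fd),
       inclusion = checkInclusion(cd$censor, config$maxCensoredFraction,
                                  config$minRemainingMinutes),
       design = design)
}
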