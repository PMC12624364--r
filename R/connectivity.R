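#' Erode a logical mask by one voxel (6-connected)
#'
#' Used to build white-matter and CSF nuisance series with limited
#' gray-matter partial-volume leakage. Falls back to the original mask if
#' erosion would empty it.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
erodeMask <- function(mask) {
  d <- dim(mask)
  m <- array(mask, d)
  shift <- function(a, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy; zs <- seq_len(d[3]) + dz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    out[which(okx), which(oky), which(okz)] <-
      a[xs[okx], ys[oky], zs[okz]]
    out
  }
  er <- m &
    shift(m, 1, 0, 0) & shift(m, -1, 0, 0) &
    shift(m, 0, 1, 0) & shift(m, 0, -1, 0) &
    shift(m, 0, 0, 1) & shift(m, 0, 0, -1)
  if (!any(er)) mask else er
}

#' Preprocess a run for functional connectivity
#'
#' On top of the standard nuisance set (trend, 18 motion parameters, spike
#' regressors), the white-matter and CSF mean series (over one-voxel-eroded
#' masks) enter the regression; the residuals are then band-passed to the
#' neuronal band (0.008-0.1 Hz by default) and demeaned per voxel.
#' Regression precedes filtering; the reverse order is available via
#' `filterFirst = TRUE`.
#'
#' @param bold a realigned [BoldRun-class].
#' @param motion frames x 6 motion trace.
#' @param masks a [SegmentationMasks-class].
#' @param bandHz FC pass band, default `c(0.008, 0.1)` Hz.
#' @param config a [pipelineConfig()].
#' @param filterFirst band-pass before the nuisance regression instead of
#'   after.
#' @return a [BoldRun-class], demeaned per voxel, band-limited.
#' @export
fcPreprocess <- function(bold, motion, masks, bandHz = c(0.008, 0.1),
                         config = pipelineConfig(), filterFirst = FALSE) {
  wmS <- globalSignal(bold, erodeMask(wmMask(masks)))
  csfS <- globalSignal(bold, erodeMask(csfMask(masks)))
  fd <- computeFD(motion, config$headRadiusMm)
  cd <- censorDesign(fd, config$fdThresholdMm, trS(bold))
  design <- nuisanceDesign(motion, cd$spikes, wmSeries = wmS,
                           csfSeries = csfS)
  bandpassRun <- function(b) {
    Y <- framesByVoxels(boldData(b))
    hi <- min(bandHz[2], 0.98 / (2 * trS(b)))
    Yf <- apply(Y, 2, butterBandpass, loHz = bandHz[1], hiHz = hi,
                trS = trS(b))
    BoldRun(voxelsTo4d(Yf, gridDim(b)), trS = trS(b),
            voxelSizeMm = voxelSizeMm(b), mask = brainMask(b))
  }
  if (filterFirst) {
    out <- nuisanceRegress(bandpassRun(bold), design)
    # remove the retained means so the output is demeaned per voxel
    Y <- framesByVoxels(boldData(out))
    Y <- sweep(Y, 2, colMeans(Y))
    out <- BoldRun(voxelsTo4d(Y, gridDim(out)), trS = trS(out),
                   voxelSizeMm = voxelSizeMm(out), mask = brainMask(out))
  } else {
    out <- bandpassRun(nuisanceRegress(bold, design))
  }
  out
}

#' Mean time series per atlas region
#'
#' @param bold a [BoldRun-class].
#' @param atlas an [AtlasLabels-class] on the same grid.
#' @return frames x regions numeric matrix (region-name columns); regions
#'   with no voxels are NA columns.
#' @export
regionTimeseries <- function(bold, atlas) {
  stopIfNot(identical(dim(atlasVolume(atlas)), gridDim(bold)),
            "atlas grid does not match the BOLD grid")
  Y <- framesByVoxels(boldData(bold))
  labs <- as.vector(atlasVolume(atlas))
  lk <- atlasLookup(atlas)
  out <- matrix(NA_real_, nrow(Y), nrow(lk),
                dimnames = list(NULL, lk$name))
  for (k in seq_len(nrow(lk))) {
    vox <- which(labs == lk$label[k])
    if (length(vox))
      out[, k] <- rowMeans(Y[, vox, drop = FALSE])
  }
  out
}

#' Seed-to-region Fisher-z functional connectivity
#'
#' For each target region other than the seed, the Fisher z-transform
#' `atanh(r)` of the Pearson correlation between the seed and target mean
#' series. `|r|` is clipped to `1 - 1e-12` before `atanh`; clipped targets
#' are flagged. Constant (zero-variance) targets yield NA.
#'
#' @param regionTs frames x regions matrix from [regionTimeseries()].
#' @param seed seed region name or column index.
#' @return data.frame of class `fcProfile`: `seed`, `target`, `r`, `z`,
#'   `flag`.
#' @export
seedConnectivity <- function(regionTs, seed) {
  stopIfNot(nrow(regionTs) >= 5, "need >= 5 frames")
  if (is.character(seed)) {
    stopIfNot(seed %in% colnames(regionTs), "unknown seed region")
    seedIdx <- match(seed, colnames(regionTs))
  } else seedIdx <- as.integer(seed)
  s <- regionTs[, seedIdx]
  stopIfNot(sd(s) > 0, "seed column is constant")
  targets <- setdiff(seq_len(ncol(regionTs)), seedIdx)
  clip <- 1 - 1e-12
  rows <- lapply(targets, function(j) {
    y <- regionTs[, j]
    if (any(is.na(y)) || sd(y) == 0)
      return(data.frame(target = colnames(regionTs)[j], r = NA_real_,
                        z = NA_real_, flag = "constant_target"))
    r <- cor(s, y)
    flag <- if (abs(r) >= clip) "clipped" else ""
    data.frame(target = colnames(regionTs)[j], r = r,
               z = atanh(max(min(r, clip), -clip)), flag = flag)
  })
  out <- do.call(rbind, rows)
  out <- cbind(seed = colnames(regionTs)[seedIdx], out)
  class(out) <- c("fcProfile", "data.frame")
  out
}
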