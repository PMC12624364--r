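#' @import methods
#' @importFrom stats coef cor cor.test lm.fit median pf pt qnorm quantile
#'   rnorm runif sd setNames var complete.cases p.adjust model.matrix
#'   spec.pgram ts
#' @importFrom utils head read.table write.table
#' @importFrom tools md5sum
NULL

#' BoldRun: a 4D BOLD time series on a regular grid
#'
#' Carrier of all voxel-level signal processing. Holds the 4D data array
#' (x, y, z, time), the repetition time in seconds, the voxel edge length in
#' millimetres, and a logical brain mask on the same spatial grid.
#'
#' @slot data 4D numeric array, dimensions (nx, ny, nz, nframes).
#' @slot trS repetition time in seconds.
#' @slot voxelSizeMm isotropic voxel edge length in millimetres.
#' @slot mask logical 3D array, same spatial grid as `data`.
#' @export
setClass("BoldRun",
  representation(data = "array", trS = "numeric",
                 voxelSizeMm = "numeric", mask = "array"))

setValidity("BoldRun", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, time)")
  if (d[4] < 2L) return("need at least 2 frames")
  if (length(object@trS) != 1L || !is.finite(object@trS) ||
      object@trS <= 0 || object@trS > 10)
    return("trS must be a single value in (0, 10] seconds")
  if (object@voxelSizeMm <= 0) return("voxelSizeMm must be positive")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask grid must match the data grid")
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' Construct a BoldRun
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param trS repetition time, seconds.
#' @param voxelSizeMm voxel edge length, millimetres.
#' @param mask logical 3D brain mask; defaults to all-true.
#' @return A [BoldRun-class] object.
#' @export
BoldRun <- function(data, trS, voxelSizeMm = 1, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  new("BoldRun", data = data, trS = trS,
      voxelSizeMm = voxelSizeMm, mask = asLogicalArray(mask))
}

asLogicalArray <- function(x) {
  y <- array(as.logical(x), dim(x))
  y
}

#' SegmentationMasks: gray matter, white matter and CSF masks
#'
#' Pairwise-disjoint tissue masks on the BOLD grid.
#'
#' @slot gm,wm,csf logical 3D arrays on a common grid.
#' @export
setClass("SegmentationMasks",
  representation(gm = "array", wm = "array", csf = "array"))

setValidity("SegmentationMasks", function(object) {
  d <- dim(object@gm)
  if (!identical(dim(object@wm), d) || !identical(dim(object@csf), d))
    return("gm, wm and csf must share one grid")
  for (nm in c("gm", "wm", "csf")) {
    m <- slot(object, nm)
    if (!is.logical(m)) return(sprintf("%s mask must be logical", nm))
    if (!any(m)) return(sprintf("%s mask is empty", nm))
  }
  if (any(object@gm & object@wm) || any(object@gm & object@csf) ||
      any(object@wm & object@csf))
    return("tissue masks must be pairwise disjoint")
  TRUE
})

#' @rdname SegmentationMasks-class
#' @param gm,wm,csf logical 3D arrays.
#' @return A [SegmentationMasks-class] object.
#' @export
SegmentationMasks <- function(gm, wm, csf) {
  new("SegmentationMasks", gm = asLogicalArray(gm),
      wm = asLogicalArray(wm), csf = asLogicalArray(csf))
}

#' AtlasLabels: integer parcellation with a name lookup
#'
#' An integer label volume (0 = unlabelled) plus a lookup table mapping each
#' nonzero label to a region name. The artifact is atlas-agnostic: any label
#' volume on the BOLD grid works.
#'
#' @slot labels integer 3D array; 0 means unlabelled.
#' @slot lookup data.frame with columns `label` (integer) and `name`.
#' @export
setClass("AtlasLabels",
  representation(labels = "array", lookup = "data.frame"))

setValidity("AtlasLabels", function(object) {
  if (!all(c("label", "name") %in% names(object@lookup)))
    return("lookup needs columns 'label' and 'name'")
  present <- sort(unique(object@labels[object@labels != 0]))
  if (!all(present %in% object@lookup$label))
    return("every nonzero label in the volume must appear in the lookup")
  if (anyDuplicated(object@lookup$label))
    return("duplicate labels in lookup")
  TRUE
})

#' @rdname AtlasLabels-class
#' @param labels integer 3D array.
#' @param lookup data.frame (`label`, `name`); defaults to `region_<k>` names.
#' @return An [AtlasLabels-class] object.
#' @export
AtlasLabels <- function(labels, lookup = NULL) {
  labels <- array(as.integer(labels), dim(labels))
  if (is.null(lookup)) {
    labs <- sort(unique(labels[labels != 0]))
    lookup <- data.frame(label = labs,
                         name = sprintf("region_%03d", labs),
                         stringsAsFactors = FALSE)
  }
  new("AtlasLabels", labels = labels, lookup = lookup)
}

#' Co2Surrogate: band-limited global-signal surrogate for arterial CO2
#'
#' The whole-brain mean BOLD signal band-limited to the respiratory
#' volume-variation band (0.02-0.04 Hz by default), demeaned, used as the
#' vasoactive-stimulus regressor for CVR estimation.
#'
#' @slot series numeric per-frame values, demeaned.
#' @slot bandHz length-2 numeric, the pass band in Hz.
#' @slot source character descriptor of the mask the signal was averaged over.
#' @export
setClass("Co2Surrogate",
  representation(series = "numeric", bandHz = "numeric", source = "character"))

setValidity("Co2Surrogate", function(object) {
  if (length(object@bandHz) != 2L || object@bandHz[1] <= 0 ||
      object@bandHz[2] <= object@bandHz[1])
    return("bandHz must be an increasing positive pair")
  if (abs(mean(object@series)) > 1e-9 * max(1, sd(object@series)))
    return("surrogate series must be demeaned")
  TRUE
})

#' CensorInfo: framewise-displacement censoring summary
#'
#' @slot fdSeries framewise displacement per frame, millimetres; first
#'   element 0 by convention (FD is a backward difference).
#' @slot keepMask logical per frame, TRUE = retained.
#' @slot censoredFraction 1 - mean(keepMask).
#' @slot remainingSeconds retained frames times TR.
#' @slot thresholdMm censoring threshold in millimetres.
#' @export
setClass("CensorInfo",
  representation(fdSeries = "numeric", keepMask = "logical",
                 censoredFraction = "numeric", remainingSeconds = "numeric",
                 thresholdMm = "numeric"))

setValidity("CensorInfo", function(object) {
  if (length(object@fdSeries) != length(object@keepMask))
    return("fdSeries and keepMask lengths differ")
  if (object@fdSeries[1] != 0) return("fdSeries[1] must be 0")
  if (abs(object@censoredFraction - (1 - mean(object@keepMask))) > 1e-12)
    return("censoredFraction inconsistent with keepMask")
  TRUE
})

#' CvrMap: voxel-wise CVR slope and its normalized (rCVR) form
#'
#' Holds the raw regression slope beta (local BOLD change per unit surrogate
#' change), the relative CVR map beta / reference, the exclusion mask from
#' inverse-tSNR thresholding, the normalization mode, and the reference beta.
#'
#' @slot beta 3D numeric array of slopes.
#' @slot rcvr 3D numeric array, `beta / referenceBeta`; NA at excluded voxels.
#' @slot excluded logical 3D array of excluded voxels.
#' @slot normalizationMode `"white_matter"` or `"global"`.
#' @slot referenceBeta scalar mean beta over the (non-excluded) reference.
#' @export
setClass("CvrMap",
  representation(beta = "array", rcvr = "array", excluded = "array",
                 normalizationMode = "character", referenceBeta = "numeric"))

setValidity("CvrMap", function(object) {
  if (!object@normalizationMode %in% c("white_matter", "global"))
    return("normalizationMode must be 'white_matter' or 'global'")
  if (!is.finite(object@referenceBeta) || object@referenceBeta <= 0)
    return("referenceBeta must be positive")
  ok <- !object@excluded
  if (any(abs(object@rcvr[ok] - object@beta[ok] / object@referenceBeta) >
          1e-9 * max(1, abs(object@referenceBeta)), na.rm = TRUE))
    return("rcvr must equal beta / referenceBeta at non-excluded voxels")
  TRUE
})

#' CombatModel: fitted empirical-Bayes location/scale harmonization model
#'
#' Persistable result of [combatFit()]: per-feature grand mean and covariate
#' coefficients, pooled SD, per-site empirical-Bayes location (gamma*) and
#' scale (delta*) effects, the site-level hyperparameters, and a convergence
#' record. Apply with [combatTransform()].
#'
#' @slot featureNames character, feature (region) labels.
#' @slot siteLevels character, the batch levels seen at fit time.
#' @slot grandMean per-feature intercept of the standardization model.
#' @slot covCoef covariates x features matrix of coefficients.
#' @slot covariateNames character, covariate column labels.
#' @slot pooledSd per-feature pooled residual SD.
#' @slot gammaStar,deltaStar sites x features EB-adjusted effects.
#' @slot gammaHat,deltaHat sites x features raw per-site effects.
#' @slot hyper list of site-level hyperparameters.
#' @slot ageMean scalar, the age value covariate centering used at fit time.
#' @slot iterations per-site iteration counts of the EB solver.
#' @export
setClass("CombatModel",
  representation(featureNames = "character", siteLevels = "character",
                 grandMean = "numeric", covCoef = "matrix",
                 covariateNames = "character", pooledSd = "numeric",
                 gammaStar = "matrix", deltaStar = "matrix",
                 gammaHat = "matrix", deltaHat = "matrix",
                 hyper = "list", ageMean = "numeric",
                 iterations = "numeric"))

setValidity("CombatModel", function(object) {
  if (any(object@deltaStar <= 0)) return("deltaStar must be positive")
  if (any(object@pooledSd <= 0)) return("pooledSd must be positive")
  TRUE
})
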