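#' @name accessors
#' @title Accessors for rsCVR classes
#' @description Slot access goes through these accessors, never `@`.
#' @param x an rsCVR object.
#' @return The slot value; see each accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setMethod("boldData", "BoldRun", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("trS", function(x) standardGeneric("trS"))
#' @rdname accessors
#' @export
setMethod("trS", "BoldRun", function(x) x@trS)

#' @rdname accessors
#' @export
setGeneric("voxelSizeMm", function(x) standardGeneric("voxelSizeMm"))
#' @rdname accessors
#' @export
setMethod("voxelSizeMm", "BoldRun", function(x) x@voxelSizeMm)

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setMethod("brainMask", "BoldRun", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("brainMask", "SegmentationMasks",
          function(x) x@gm | x@wm | x@csf)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "BoldRun", function(x) dim(x@data)[4])

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setMethod("gridDim", "BoldRun", function(x) dim(x@data)[1:3])

#' @rdname accessors
#' @export
setGeneric("gmMask", function(x) standardGeneric("gmMask"))
#' @rdname accessors
#' @export
setMethod("gmMask", "SegmentationMasks", function(x) x@gm)
#' @rdname accessors
#' @export
setGeneric("wmMask", function(x) standardGeneric("wmMask"))
#' @rdname accessors
#' @export
setMethod("wmMask", "SegmentationMasks", function(x) x@wm)
#' @rdname accessors
#' @export
setGeneric("csfMask", function(x) standardGeneric("csfMask"))
#' @rdname accessors
#' @export
setMethod("csfMask", "SegmentationMasks", function(x) x@csf)

#' @rdname accessors
#' @export
setGeneric("atlasVolume", function(x) standardGeneric("atlasVolume"))
#' @rdname accessors
#' @export
setMethod("atlasVolume", "AtlasLabels", function(x) x@labels)
#' @rdname accessors
#' @export
setGeneric("atlasLookup", function(x) standardGeneric("atlasLookup"))
#' @rdname accessors
#' @export
setMethod("atlasLookup", "AtlasLabels", function(x) x@lookup)
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setMethod("nRegions", "AtlasLabels", function(x) nrow(x@lookup))

#' @rdname accessors
#' @export
setGeneric("surrogateSeries", function(x) standardGeneric("surrogateSeries"))
#' @rdname accessors
#' @export
setMethod("surrogateSeries", "Co2Surrogate", function(x) x@series)
#' @rdname accessors
#' @export
setGeneric("bandHz", function(x) standardGeneric("bandHz"))
#' @rdname accessors
#' @export
setMethod("bandHz", "Co2Surrogate", function(x) x@bandHz)

#' @rdname accessors
#' @export
setGeneric("fdSeries", function(x) standardGeneric("fdSeries"))
#' @rdname accessors
#' @export
setMethod("fdSeries", "CensorInfo", function(x) x@fdSeries)
#' @rdname accessors
#' @export
setGeneric("keepMask", function(x) standardGeneric("keepMask"))
#' @rdname accessors
#' @export
setMethod("keepMask", "CensorInfo", function(x) x@keepMask)
#' @rdname accessors
#' @export
setGeneric("censoredFraction", function(x) standardGeneric("censoredFraction"))
#' @rdname accessors
#' @export
setMethod("censoredFraction", "CensorInfo", function(x) x@censoredFraction)
#' @rdname accessors
#' @export
setGeneric("remainingSeconds", function(x) standardGeneric("remainingSeconds"))
#' @rdname accessors
#' @export
setMethod("remainingSeconds", "CensorInfo", function(x) x@remainingSeconds)

#' @rdname accessors
#' @export
setGeneric("betaVolume", function(x) standardGeneric("betaVolume"))
#' @rdname accessors
#' @export
setMethod("betaVolume", "CvrMap", function(x) x@beta)
#' @rdname accessors
#' @export
setGeneric("rcvrVolume", function(x) standardGeneric("rcvrVolume"))
#' @rdname accessors
#' @export
setMethod("rcvrVolume", "CvrMap", function(x) x@rcvr)
#' @rdname accessors
#' @export
setGeneric("excludedMask", function(x) standardGeneric("excludedMask"))
#' @rdname accessors
#' @export
setMethod("excludedMask", "CvrMap", function(x) x@excluded)
#' @rdname accessors
#' @export
setGeneric("referenceBeta", function(x) standardGeneric("referenceBeta"))
#' @rdname accessors
#' @export
setMethod("referenceBeta", "CvrMap", function(x) x@referenceBeta)
#' @rdname accessors
#' @export
setGeneric("normalizationMode", function(x) standardGeneric("normalizationMode"))
#' @rdname accessors
#' @export
setMethod("normalizationMode", "CvrMap", function(x) x@normalizationMode)

#' @rdname accessors
#' @export
setGeneric("gammaStar", function(x) standardGeneric("gammaStar"))
#' @rdname accessors
#' @export
setMethod("gammaStar", "CombatModel", function(x) x@gammaStar)
#' @rdname accessors
#' @export
setGeneric("deltaStar", function(x) standardGeneric("deltaStar"))
#' @rdname accessors
#' @export
setMethod("deltaStar", "CombatModel", function(x) x@deltaStar)
#' @rdname accessors
#' @export
setGeneric("siteLevels", function(x) standardGeneric("siteLevels"))
#' @rdname accessors
#' @export
setMethod("siteLevels", "CombatModel", function(x) x@siteLevels)

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldRun: %d x %d x %d grid, %d frames, TR %.3g s, voxel %.3g mm\n",
              d[1], d[2], d[3], d[4], object@trS, object@voxelSizeMm))
  cat(sprintf("  brain mask: %d voxels\n", sum(object@mask)))
})

setMethod("show", "SegmentationMasks", function(object) {
  cat(sprintf("SegmentationMasks: GM %d, WM %d, CSF %d voxels\n",
              sum(object@gm), sum(object@wm), sum(object@csf)))
})

setMethod("show", "AtlasLabels", function(object) {
  cat(sprintf("AtlasLabels: %d regions, %d labelled voxels\n",
              nrow(object@lookup), sum(object@labels != 0)))
})

setMethod("show", "Co2Surrogate", function(object) {
  cat(sprintf("Co2Surrogate: %d frames, band %.3g-%.3g Hz, source '%s'\n",
              length(object@series), object@bandHz[1], object@bandHz[2],
              object@source))
})

setMethod("show", "CensorInfo", function(object) {
  cat(sprintf(
    "CensorInfo: %d/%d frames censored (%.1f%%), %.1f s remaining, FD > %.3g mm\n",
    sum(!object@keepMask), length(object@keepMask),
    100 * object@censoredFraction, object@remainingSeconds,
    object@thresholdMm))
})

setMethod("show", "CvrMap", function(object) {
  cat(sprintf("CvrMap: %s-normalized, reference beta %.4g, %d voxels excluded\n",
              object@normalizationMode, object@referenceBeta,
              sum(object@excluded)))
})

setMethod("show", "CombatModel", function(object) {
  cat(sprintf(
    "CombatModel: %d features, %d sites, covariates [%s], max %d EB iterations\n",
    length(object@featureNames), length(object@siteLevels),
    paste(object@covariateNames, collapse = ", "),
    as.integer(max(object@iterations))))
})
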