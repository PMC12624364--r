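#' Pipeline configuration
#'
#' Defaults are the analysis's printed parameters: CVR band 0.02-0.04 Hz,
#' FC band 0.008-0.1 Hz, FD censoring threshold 0.25 mm, inclusion rules
#' (< 25% frames censored and >= 4 minutes remaining), 8 mm FWHM smoothing,
#' 98th-percentile inverse-tSNR exclusion, white-matter normalization, and
#' a 50 mm head radius for the FD rotation term. Every field is
#' overridable; the config is echoed (with a hash) into every output.
#'
#' @param bandCvrHz CVR surrogate pass band, Hz.
#' @param bandFcHz FC pass band, Hz.
#' @param fdThresholdMm FD censoring threshold, mm.
#' @param maxCensoredFraction inclusion bound on the censored fraction.
#' @param minRemainingMinutes inclusion bound on remaining data, minutes.
#' @param smoothingFwhmMm Gaussian smoothing FWHM, mm.
#' @param itsnrPercentile inverse-tSNR exclusion percentile (100 disables).
#' @param normalizationMode `"white_matter"` or `"global"`.
#' @param headRadiusMm FD rotation-to-displacement radius, mm.
#' @param rngSeed integer seed for any stochastic stage.
#' @return a named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(bandCvrHz = c(0.02, 0.04),
                           bandFcHz = c(0.008, 0.1),
                           fdThresholdMm = 0.25,
                           maxCensoredFraction = 0.25,
                           minRemainingMinutes = 4,
                           smoothingFwhmMm = 8,
                           itsnrPercentile = 98,
                           normalizationMode = c("white_matter", "global"),
                           headRadiusMm = 50,
                           rngSeed = 1L) {
  normalizationMode <- match.arg(normalizationMode)
  structure(list(bandCvrHz = bandCvrHz, bandFcHz = bandFcHz,
                 fdThresholdMm = fdThresholdMm,
                 maxCensoredFraction = maxCensoredFraction,
                 minRemainingMinutes = minRemainingMinutes,
                 smoothingFwhmMm = smoothingFwhmMm,
                 itsnrPercentile = itsnrPercentile,
                 normalizationMode = normalizationMode,
                 headRadiusMm = headRadiusMm,
                 rngSeed = as.integer(rngSeed)),
            class = "pipelineConfig")
}

#' Hash a pipeline configuration
#'
#' MD5 of the config's canonical JSON form; stamped into output tables and
#' the run manifest for provenance.
#'
#' @param config a [pipelineConfig()].
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates preprocess -> rCVR -> (optional seed FC) -> inclusion
#' filtering -> harmonization -> group statistics. Image-bearing cohorts
#' (from `makeCohort(images = TRUE)`) are processed one subject at a time;
#' feature-level cohorts skip the voxel stages and feed their regional
#' features directly to harmonization. Subjects failing the inclusion
#' rules are dropped before harmonization with their reasons logged in the
#' manifest.
#'
#' @param cohort a `syntheticCohort` from [makeCohort()].
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory; when given, feature tables,
#'   QC and stats TSVs, the config echo and the manifest JSON are written.
#' @param fcSeed optional seed region name; when given, seed FC profiles
#'   are computed (image cohorts only) and harmonized in a separate model.
#' @return list of class `runManifest`: `qc` (per-subject QC table),
#'   `included`, `features` (harmonized `SummarizedExperiment`),
#'   `combatModel`, `regionStats`, `posthocStats`, `fc` (if requested),
#'   `configHash`, `config`, `outputs` (paths written).
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL,
                        fcSeed = NULL) {
  hash <- configHash(config)
  pheno <- cohort$phenotypes
  hasImages <- !is.null(cohort$subjects)
  qc <- data.frame(subject_id = pheno$subject_id,
                   mean_fd = pheno$mean_fd,
                   censored_fraction = 0,
                   remaining_minutes = NA_real_,
                   include = TRUE, reasons = "",
                   stringsAsFactors = FALSE)
  fcTab <- NULL
  if (hasImages) {
    feats <- NULL
    fcRows <- list()
    for (i in seq_along(cohort$subjects)) {
      sub <- cohort$subjects[[i]]
      pp <- preprocessBold(sub$bold, sub$motion, config)
      qc$mean_fd[i] <- pp$meanFd
      qc$censored_fraction[i] <- censoredFraction(pp$censor)
      qc$remaining_minutes[i] <- remainingSeconds(pp$censor) / 60
      qc$include[i] <- pp$inclusion$include
      qc$reasons[i] <- paste(pp$inclusion$reasons, collapse = "; ")
      rc <- computeRcvr(pp$bold, sub$masks, sub$atlas, config)
      if (is.null(feats))
        feats <- matrix(NA_real_, length(rc$regional),
                        length(cohort$subjects),
                        dimnames = list(names(rc$regional),
                                        pheno$subject_id))
      feats[, i] <- rc$regional
      if (!is.null(fcSeed)) {
        fcBold <- fcPreprocess(sub$bold, sub$motion, sub$masks,
                               config$bandFcHz, config)
        rts <- regionTimeseries(fcBold, sub$atlas)
        prof <- seedConnectivity(rts, fcSeed)
        fcRows[[i]] <- setNames(prof$z, prof$target)
      }
    }
    pheno$mean_fd <- qc$mean_fd
    if (!is.null(fcSeed)) fcTab <- do.call(rbind, fcRows)
  } else {
    feats <- cohort$features
  }

  keep <- qc$include
  stopIfNot(sum(keep) >= 4, "fewer than 4 subjects pass inclusion")
  se <- regionalFeatures(feats[, keep, drop = FALSE],
                         pheno[keep, , drop = FALSE])
  harm <- combatHarmonize(se)
  regionStats <- regionEffects(harm$se)
  posthoc <- subgroupEffects(harm$se, split = "sex", term = "diagnosis")

  fcOut <- NULL
  if (!is.null(fcTab)) {
    fcSe <- regionalFeatures(t(fcTab[keep, , drop = FALSE]),
                             pheno[keep, , drop = FALSE])
    fcHarm <- combatHarmonize(fcSe)       # separate model per feature family
    fcOut <- list(se = fcHarm$se, model = fcHarm$model)
  }

  outputs <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      p <- file.path(outDir, name)
      con <- file(p, "w")
      writeLines(sprintf("# config_hash: %s", hash), con)
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      p
    }
    outputs <- c(
      wt(qc, "qc.tsv"),
      wt(regionStats, "region_stats.tsv"),
      wt(posthoc, "posthoc_stats.tsv"))
    fp <- file.path(outDir, "features_harmonized.tsv")
    writeFeatureTable(harm$se, fp)
    cfgPath <- file.path(outDir, "config.json")
    jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                         cfgPath, digits = NA, auto_unbox = TRUE)
    outputs <- c(outputs, fp, cfgPath)
  }

  manifest <- structure(list(
    qc = qc, included = pheno$subject_id[keep], features = harm$se,
    combatModel = harm$model, regionStats = regionStats,
    posthocStats = posthoc, fc = fcOut, configHash = hash,
    config = config, outputs = outputs), class = "runManifest")
  if (!is.null(outDir)) {
    mPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(
      list(config_hash = hash, included = manifest$included,
           excluded = setdiff(pheno$subject_id, manifest$included),
           exclusion_reasons = qc$reasons[!keep],
           outputs = outputs),
      mPath, auto_unbox = TRUE)
    manifest$outputs <- c(outputs, mPath)
  }
  manifest
}
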