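#' Read a 4D BOLD NIfTI file
#'
#' TR is taken from the time-axis spacing of the header; pass `trS` to
#' override (required when the header carries no TR).
#'
#' @param path NIfTI file path.
#' @param trS optional repetition-time override, seconds.
#' @return a [BoldRun-class].
#' @export
readBold <- function(path, trS = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  trHdr <- hdr$pixdim[5]
  if (is.null(trS)) {
    if (!is.finite(trHdr) || trHdr <= 0)
      stop("no TR in the NIfTI header and no trS override given: ", path,
           call. = FALSE)
    trS <- trHdr
  }
  BoldRun(array(as.numeric(arr), dim(arr)), trS = trS,
          voxelSizeMm = hdr$pixdim[2])
}

#' Write a BOLD run (or a 3D volume) as NIfTI
#'
#' @param x a [BoldRun-class], or a 3D/4D numeric array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param voxelSizeMm voxel edge length for bare arrays.
#' @param trS time-axis spacing for bare 4D arrays.
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, voxelSizeMm = 1, trS = 1) {
  if (is(x, "BoldRun")) {
    arr <- boldData(x); voxelSizeMm <- voxelSizeMm(x); trS <- trS(x)
  } else arr <- x
  nd <- length(dim(arr))
  pd8 <- c(-1, rep(voxelSizeMm, 3), trS, 0, 0, 0)
  img <- RNifti::asNifti(arr, reference = list(pixdim = pd8))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.numeric(arr), dim(arr))
}

#' Read / write a 6-column motion-parameter trace
#'
#' Whitespace-delimited text, one row per frame: 3 translations (mm) then
#' 3 rotations (radians).
#'
#' @param path text file path.
#' @return frames x 6 numeric matrix.
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  stopIfNot(ncol(m) == 6, "motion trace file must have 6 columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname readMotionTrace
#' @param motion frames x 6 numeric matrix.
#' @export
writeMotionTrace <- function(motion, path) {
  write.table(format(motion, digits = 10), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate (and read) a phenotype table
#'
#' Required columns: `subject_id`, `site`, `diagnosis` (`ASD` or `NA`,
#' the literal label for non-autistic), `sex` (`F`/`M`), `age` (years,
#' positive). Optional: `mean_fd` (mm), `iq` (may be empty). Unknown
#' category levels and duplicate subject ids are errors naming the
#' offending rows.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readPhenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", na.strings = "",
                   colClasses = "character", quote = "")
  need <- c("subject_id", "site", "diagnosis", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$age <- as.numeric(df$age)
  if ("mean_fd" %in% names(df)) df$mean_fd <- as.numeric(df$mean_fd)
  if ("iq" %in% names(df)) df$iq <- suppressWarnings(as.numeric(df$iq))
  validatePhenotypes(df)
}

#' @rdname readPhenotypes
#' @param pheno a phenotype data.frame to validate.
#' @export
validatePhenotypes <- function(pheno) {
  badDx <- which(!pheno$diagnosis %in% c("ASD", "NA"))
  if (length(badDx))
    stop("unknown diagnosis value(s) at row(s) ",
         paste(badDx, collapse = ", "), ": ",
         paste(unique(pheno$diagnosis[badDx]), collapse = ", "),
         call. = FALSE)
  badSex <- which(!pheno$sex %in% c("F", "M"))
  if (length(badSex))
    stop("unknown sex value(s) at row(s) ",
         paste(badSex, collapse = ", "), call. = FALSE)
  dup <- pheno$subject_id[duplicated(pheno$subject_id)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(is.na(pheno$age) | pheno$age <= 0))
    stop("age must be positive for every subject", call. = FALSE)
  if (any(is.na(pheno$subject_id) | is.na(pheno$site)))
    stop("subject_id and site must be non-missing", call. = FALSE)
  pheno
}

#' @rdname readPhenotypes
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a regional feature table (TSV)
#'
#' On disk: rows are subjects (first column `subject_id`), remaining
#' columns are region names. In memory the package uses regions x subjects
#' matrices (see [regionalFeatures()]).
#'
#' @param path TSV path.
#' @return regions x subjects numeric matrix.
#' @export
readFeatureTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "")
  ids <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- ids
  m
}

#' @rdname readFeatureTable
#' @param features regions x subjects matrix (or a `SummarizedExperiment`).
#' @export
writeFeatureTable <- function(features, path) {
  if (is(features, "SummarizedExperiment"))
    features <- featureMatrix(features)
  df <- data.frame(subject_id = colnames(features),
                   t(features), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a cohort truth manifest (JSON)
#'
#' The manifest records every injected effect (base profile, group
#' effects, site effects, per-subject biological features, seed), so
#' recovery tests can read the truth instead of re-deriving it. The
#' round-trip is lossless to full double precision.
#'
#' @param truth a `cohortTruth` list from [makeCohort()].
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeCohortTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCohortTruth
#' @export
readCohortTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("groupEffects", "bioFeatures", "siteAdditive",
               "siteMultiplicative"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.matrix(x[[nm]])
  structure(x, class = "cohortTruth")
}

#' Persist / restore a fitted harmonization model (JSON)
#'
#' @param model a [CombatModel-class].
#' @param path JSON path.
#' @return the path, invisibly (write) or the model (read).
#' @export
writeCombatModel <- function(model, path) {
  payload <- list(
    featureNames = model@featureNames, siteLevels = model@siteLevels,
    grandMean = model@grandMean, covCoef = model@covCoef,
    covariateNames = model@covariateNames, pooledSd = model@pooledSd,
    gammaStar = model@gammaStar, deltaStar = model@deltaStar,
    gammaHat = model@gammaHat, deltaHat = model@deltaHat,
    hyper = model@hyper, ageMean = model@ageMean,
    iterations = model@iterations)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCombatModel
#' @export
readCombatModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(m) as.matrix(m)
  new("CombatModel", featureNames = x$featureNames,
      siteLevels = x$siteLevels, grandMean = x$grandMean,
      covCoef = mat(x$covCoef), covariateNames = x$covariateNames,
      pooledSd = x$pooledSd, gammaStar = mat(x$gammaStar),
      deltaStar = mat(x$deltaStar), gammaHat = mat(x$gammaHat),
      deltaHat = mat(x$deltaHat), hyper = as.list(x$hyper),
      ageMean = x$ageMean, iterations = x$iterations)
}

#' Write one synthetic subject to a directory
#'
#' Emits `bold.nii.gz`, `mask_gm/wm/csf.nii.gz`, `atlas.nii.gz`,
#' `motion.par` (6-column text) and `phenotype.tsv`.
#'
#' @param subject a `syntheticSubject` from [makeSubject()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- voxelSizeMm(subject$bold)
  writeVolume(subject$bold, file.path(dir, "bold.nii.gz"))
  writeVolume(array(as.numeric(gmMask(subject$masks)),
                    dim(gmMask(subject$masks))),
              file.path(dir, "mask_gm.nii.gz"), voxelSizeMm = vs)
  writeVolume(array(as.numeric(wmMask(subject$masks)),
                    dim(wmMask(subject$masks))),
              file.path(dir, "mask_wm.nii.gz"), voxelSizeMm = vs)
  writeVolume(array(as.numeric(csfMask(subject$masks)),
                    dim(csfMask(subject$masks))),
              file.path(dir, "mask_csf.nii.gz"), voxelSizeMm = vs)
  writeVolume(array(as.numeric(atlasVolume(subject$atlas)),
                    dim(atlasVolume(subject$atlas))),
              file.path(dir, "atlas.nii.gz"), voxelSizeMm = vs)
  writeMotionTrace(subject$motion, file.path(dir, "motion.par"))
  if (!is.null(subject$phenotype))
    writePhenotypes(subject$phenotype, file.path(dir, "phenotype.tsv"))
  invisible(dir)
}
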