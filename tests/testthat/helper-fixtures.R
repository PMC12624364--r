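# Shared small fixtures, built in code at test time.

smallAcq <- function(noiseSd = 0, nFrames = 150) {
  acquisitionConfig(nFrames = nFrames, trS = 2.5,
                    gridShape = c(12L, 12L, 12L), voxelSizeMm = 4,
                    noiseSd = noiseSd)
}

smallTruth <- function(nRegions = 12L, seed = 1, ...) {
  subjectTruth(nRegions = nRegions, seed = seed, ...)
}

# config used for exact analytic-composition checks: no smoothing (which
# mixes neighbouring parcels) and no itSNR exclusion (degenerate on
# noiseless data)
exactConfig <- function() {
  pipelineConfig(smoothingFwhmMm = 0, itsnrPercentile = 100)
}

quietPreprocess <- function(...) suppressMessages(preprocessBold(...))

smallPheno <- function(n, nSites = 2, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%04d", seq_len(n)),
             site = sprintf("site_%02d", rep_len(seq_len(nSites), n)),
             diagnosis = sample(rep_len(c("ASD", "NA"), n)),
             sex = sample(rep_len(c("F", "M"), n)),
             age = runif(n, 9, 12),
             mean_fd = runif(n, 0.05, 0.2),
             stringsAsFactors = FALSE)
}
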