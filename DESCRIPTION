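Package: rsCVR
Title: Resting-State Relative Cerebrovascular Reactivity Mapping and
    Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps relative cerebrovascular reactivity (rCVR) from
    resting-state BOLD fMRI without gas challenges, using the 0.02-0.04 Hz
    band-limited global signal as a surrogate for arterial CO2 fluctuation.
    Provides motion-parameter expansion and framewise-displacement spike
    censoring, Gaussian smoothing, voxel-wise CVR regression with
    inverse-tSNR exclusion and white-matter (or global) normalization,
    atlas-based regional averaging, seed-based Fisher-z functional
    connectivity, empirical-Bayes multi-site (ComBat) harmonization of
    regional features, and region-wise diagnosis-by-sex general linear
    models with Benjamini-Hochberg false-discovery-rate control. A
    multi-site synthetic BOLD cohort generator with a full ground-truth
    manifest supports recovery and calibration studies at every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    signal,
    jsonlite,
    tools,
    S4Vectors,
    SummarizedExperiment
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
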