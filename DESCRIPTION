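Package: seedprint
Title: Seed-Based Resting-State Connectivity Fingerprinting of Task-Defined Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for testing whether the resting-state
    functional connectivity of a seed region (the dorsal anterior cingulate
    cortex) precisely targets brain regions defined by an independent task
    localizer. Provides NIfTI volume and parcel-atlas handling, a synthetic
    multi-subject fMRI cohort generator with planted, subject-specific
    connectivity and activation structure, rest preprocessing (smoothing,
    band-pass filtering, motion censoring, nuisance and common-ROI-variance
    regression), seed-based voxelwise correlation with Fisher z-transform and
    group t-tests, Monte-Carlo cluster-extent correction, block-design GLM
    fitting with a gamma haemodynamic response function, percentile-threshold
    overlap curves, and a within- versus between-subject spatial-correlation
    fingerprint analysis with split-half reliability and repeated-measures
    ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
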