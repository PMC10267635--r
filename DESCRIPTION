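Package: mmfpipe
Title: Mismatch-Field Analysis Pipeline for Multi-Feature Auditory Oddball MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of auditory mismatch fields (MMF) in
    multi-feature oddball MEG experiments: stimulus-sequence and tone
    generation for the alternating (Optimum-1 style) paradigm, a
    single-sphere current-dipole forward model with an axial-gradiometer
    array, a synthetic-cohort simulator with known ground-truth mismatch
    effects, zero-phase FIR preprocessing and epoching, cross-validated
    effect-matched spatial (EMS) filtering, nonparametric cluster-based
    permutation tests (one-sample, paired, independent) with a mean-t
    cluster statistic, LCMV beamformer source reconstruction with
    centroid-proximity ROI filters, and group estimation statistics
    (permutation tests, Cohen's d with BCa bootstrap intervals, Pearson
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
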