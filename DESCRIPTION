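Package: humordec
Title: Lag-Resolved Decoding of Subjective Humor Experiences from fMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.invalid",
    role = c("aut", "cre"))
Description: Tools for decoding subjective experiences, reported continuously
    during naturalistic movie viewing, from multi-voxel fMRI activity patterns.
    Continuous slider reports (and alternative behavioral signals such as
    facial-marker motion or audience-laughter annotations) are converted into
    lag-resolved event labels on a 2 s bin grid; per-region, per-lag linear
    decoders are trained as balanced-subsampling ensembles of hinge-loss
    support vector machines and evaluated with leave-one-run-out ROC/AUC;
    group-level inference uses t-tests with Benjamini-Hochberg false discovery
    rate correction.  A synthetic-data module simulates multi-subject
    movie-viewing and device-manipulation control experiments with known
    ground-truth event times, HRF-convolved anticipatory signals and AR(1)
    noise, so the full pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    RNifti,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
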