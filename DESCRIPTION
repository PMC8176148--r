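Package: megconn
Title: Resting-State MEG Band Power, Envelope Connectomes and Group
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state MEG group studies at the
    source level. Simulates cohorts of multichannel MEG-like recordings with
    plantable group effects, cleans and epochs continuous data (Butterworth
    band-pass, FFT notch, ICA artifact attenuation, motion and jump
    rejection), reconstructs virtual-sensor time series at atlas seed
    locations with an LCMV beamformer over a spherical head model, computes
    Welch band power and leakage-corrected amplitude-envelope-correlation
    (AEC) connectomes via symmetric orthogonalization, runs covariate-adjusted
    permutation ANCOVA with Benjamini-Hochberg FDR, and compares regional
    power against functional connectivity as discriminative markers through a
    nested recursive random-forest feature selection and SVM/PLS-DA
    classification workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    ranger,
    pROC,
    mixOmics,
    cluster,
    yaml,
    jsonlite,
    rlang,
    pheatmap,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
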