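Package: stefi
Title: Single-Trial EEG-Informed fMRI Analysis with Data-Driven
    Independent Component Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coupling single-trial EEG amplitude variability to
    fMRI BOLD responses in simultaneous EEG/fMRI experiments. Implements an
    automated, data-driven procedure that classifies independent components
    (ICs) of the EEG by pointwise reliability statistics (t-values
    standardized to per-trial Z scores), selects latency ranges wholly
    contained in participant-specific analysis windows anchored on the
    median response time, extracts polarity-corrected single-trial
    amplitudes, converts them into fMRI regressors (cubic smoothing spline
    resampling, inter-quartile-range normalization, canonical HRF
    convolution, orthogonalization to onset regressors), and fits voxelwise
    general linear models with cluster-extent thresholding. Includes EEG
    preprocessing (gradient-artifact template subtraction, bandpass
    filtering, extended-infomax ICA, ballistocardiogram and ocular artifact
    IC flagging), readers and writers for BrainVision EEG, BIDS-style event
    tables and NIfTI volumes, and a synthetic simultaneous-EEG/fMRI
    generator with planted ground truth for end-to-end validation.
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
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
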