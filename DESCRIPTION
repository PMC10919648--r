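Package: cogsim
Title: EEG-fMRI Similarity Analysis for Cognitive-State Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing cognitive state from simultaneous EEG-fMRI
    recordings of programmers performing code comprehension and bug-inspection
    tasks. Implements a 2,100-descriptor EEG feature bank (statistical, Hjorth,
    spectral band power and ratio, Higuchi fractal dimension and Hurst exponent
    features in 1-second windows), second-order aggregation to the fMRI
    repetition-time grid, convolution with a canonical double-gamma hemodynamic
    response function over a grid of hemodynamic delays, voxelwise Pearson
    correlation maps with Benjamini-Hochberg false-discovery-rate correction,
    an overlap-portion metric against a volume of interest, per-subject
    hemodynamic-delay optimization, feature ranking with an elbow cutoff, and
    individual and group occurrence summaries. A synthetic-data generator with
    planted latent cognitive load, responsive channels/band and hemodynamic
    delay makes the full pipeline verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
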