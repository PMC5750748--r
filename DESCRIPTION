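Package: eegmra
Title: Single-Channel EEG Artifact Identification via Time-Frequency
    Two-Dimensional Multi-Resolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies ocular and facial-muscle artifacts in single-channel
    EEG. One-second segments are mapped to quadratic time-frequency images
    (Cohen's-class distributions with six kernels, including the smoothed
    Wigner-Ville distribution), decomposed by two-dimensional multi-resolution
    analysis (four-level Haar wavelet and a five-scale wrapping curvelet
    transform), and summarized by gray-level co-occurrence and moment features
    feeding multi-class classifiers (RBF support vector machine, information-gain
    decision tree, 1-nearest neighbour) under stratified ten-fold
    cross-validation. Includes a labelled synthetic EEG artifact generator,
    principal-component reduction, exact one-tailed Wilcoxon signed-rank
    comparison of methods, and an end-to-end pipeline with EDF and CSV input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    rpart,
    jsonlite
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
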