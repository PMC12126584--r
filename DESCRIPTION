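Package: pdmotor
Title: Motor Symptom Estimation from Wrist Accelerometer Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Parkinson's disease motor symptom presence and severity
    (tremor on an ordinal 0 to "3-4" scale, bradykinesia and dyskinesia as
    presence/absence) from tri-axial wrist accelerometer recordings. Provides a
    synthetic cohort simulator with realistic task, tremor, bradykinesia and
    dyskinesia signal components; sliding-window segmentation with label
    cleaning; grouped stratified data splitting and a random-search driver; a
    random convolutional kernel transform classifier with PPV/max pooling and a
    cross-validated ridge head; a compact Inception-style convolutional network
    ensemble; a 70-feature wavelet baseline with a small multi-layer
    perceptron; evaluation metrics including balanced accuracy, average
    precision, one-vs-one AUROC, macro-averaged mean absolute error and
    smoothed expected calibration error; almost-stochastic-order significance
    testing with bootstrap power analysis; and a task-level misclassification
    analysis with Welch spectral and sample-entropy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
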