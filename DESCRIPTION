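Package: spastemg
Title: Spasticity Grading from Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated Modified Ashworth Scale (MAS) grading of post-stroke
    elbow-flexor spasticity from three-channel surface electromyography (sEMG)
    recorded during passive flexion-extension. Implements the full pipeline:
    20-450 Hz band-pass and 48-52 Hz notch preprocessing, per-segment
    time-domain (RMS, integrated EMG, spline-envelope area) and
    frequency-domain (mean and median power frequency) feature extraction,
    max-min normalization, Spearman screening of features against the MAS
    ordinal, correlation-derived channel weights and multichannel feature
    fusion, and a k-nearest-neighbour classifier selected and evaluated by
    stratified 10-fold cross-validation. A synthetic-cohort generator emulates
    the recording protocol so the pipeline is fully testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
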