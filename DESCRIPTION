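Package: stabselect
Title: Stability-Aware Feature Selection for Small-Sample Movement
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building reliable classifiers from small-sample,
    high-dimensional movement and eye-tracking data. Provides a synthetic
    cohort generator with planted group effects, kinematic and gaze feature
    extraction, leakage-free preprocessing (sample-size-dependent outlier
    trimming, group-mean imputation, training-set z-scoring), seven feature
    selection methods including a stability-driven wrapped t-test selector,
    Kuncheva's stability index, nested cross-validated SVM evaluation with
    independent-sample testing, and permutation significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
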