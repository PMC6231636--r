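Package: mindwander
Title: Mind-Wandering Detection from Driving Behavior Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probe-caught mind-wandering detection in simulated
    car-following tasks. Generates labeled multichannel driving sessions with
    a configurable cohort simulator, assembles the four analysis channels
    (lane offset, relative steering, foot operation, headway distance),
    applies z-score and independent-component preprocessing, extracts global
    session-level and local pre-probe window features (summary statistics,
    linear trends, Shannon entropy, autoregressive coefficients, Haar wavelet
    variances), and runs driver-independent leave-one-participant-out and
    driver-dependent repeated stratified k-fold classification grids over six
    classifier families. Evaluation includes Cohen's kappa with permutation
    significance, accuracy, precision, recall, tie-corrected Friedman model
    comparison with Nemenyi post-hoc tests, and exact sign tests on median
    kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    class,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
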