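Package: tempocsp
Title: Temporal Combination Pattern Optimization for Motor-Imagery EEG
    Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes two-class motor-imagery EEG by decomposing each trial
    into five overlapping cue-locked time segments, extracting common
    spatial pattern (CSP) log-variance features per segment, and selecting
    an optimal temporal combination of those features with one of four
    selectors: Parzen-window mutual information (MUIN), LASSO, PCA, or
    stepwise linear discriminant analysis (SWLDA). Selected features are
    classified with a support vector machine under repeated stratified
    cross-validation. Includes event-related spectral perturbation (ERSP)
    time-frequency analysis and a synthetic generator of lateralized
    event-related desynchronization (ERD) EEG for end-to-end testing
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
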