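Package: spemeta
Title: Local Confidence and Global Self-Performance Estimates in Perceptual Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how global
    self-performance estimates (SPEs) arise from local decision confidence in
    a two-alternative perceptual discrimination task. Provides a parameterized
    signal-detection-theory observer that generates complete behavioral
    sessions (psychometric calibration, a blocked main task with end-of-block
    task choices, and a confidence-rating metacognition session); maximum
    likelihood fitting of cumulative-normal psychometric functions with
    inversion to target-accuracy stimulus levels; type-1 and type-2
    signal-detection metrics including maximum likelihood meta-d', the M-ratio
    and the type-2 ROC area (AUROC2); ordinal (cumulative-link) regression of
    confidence ratings on trial features with cross-session transfer to
    predicted trial-wise confidence; and block-level task-choice analyses
    (choice frequencies, logistic regressions, deviance-based model comparison
    and a default-prior JZS Bayes factor).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
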