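Package: stepcalib
Title: Subliminal Threshold Estimation Procedure (STEP) and Adaptive
    Calibration Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Adaptive calibration of subliminal stimulus intensities for
    two-alternative forced-choice (2AFC) masked-priming experiments. Implements
    the Subliminal Threshold Estimation Procedure (STEP), a 1-up 1-down
    staircase augmented with cumulative-weighted incorrect-response (CWIR)
    threshold estimation, integration of a binary subjective visibility report,
    and a dynamic upper boundary driven by sequential one-tailed binomial
    tests. Ships a virtual-participant simulator built on a two-part Weibull
    objective psychometric function and a logistic subjective visibility
    function, reference calibration methods (fixed- and adaptive-step
    staircases, PEST, QUEST, accelerated stochastic approximation), a
    population-scale Monte-Carlo benchmark with RMSE, NRMSE and PRMSE error
    metrics, per-participant MAP psychometric fitting, and a command-line
    interface with an interactive trial protocol for driving real experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
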