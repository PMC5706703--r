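Package: catchnet
Title: Bayesian Cue-Weighting Analysis for Sensorimotor Estimation Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sensorimotor estimation ("candy-catching")
    experiments in which a hidden target drawn from a Gaussian prior must be
    located from a small sample of noisy cues (the "splash"). Provides the
    Bayesian ideal-observer benchmark (posterior mean, optimal reliance
    weight, chance-level performance), a synthetic-cohort simulator with
    configurable reliance weights, motor noise and lapses, through-origin
    estimation-slope fitting with bootstrap confidence intervals, and
    rank-based group inference (exact Wilcoxon signed-rank and the
    Scheirer-Ray-Hare factorial rank test), plus CSV/JSON input-output and a
    reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
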