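Package: dualroute
Title: Evidence-Accumulation Models of Distractor Effects in Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulators for four evidence-accumulation race models
    of three-alternative value-based choice (mutual inhibition, divisive
    normalisation, a parallel dual route combining both, and a two-option
    null model), together with the analysis tool chain used to study how an
    unavailable distractor option alters decisions between two choosable
    options: decision-space simulation sweeps, a suite of per-participant
    choice and gaze regressions with group-level tests, simulation-based
    model fitting with random-effects Bayesian model selection, synthetic
    task schedules and behaviour, artefact-control simulations, and fixation
    and gaze-shift feature extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    nnet,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
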