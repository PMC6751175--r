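Package: causalbind
Title: Bayesian Causal-Inference Model of Action-Outcome Temporal Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and estimator for a Bayesian cue-integration account
    of the sense of agency. Provides closed-form maximum-a-posteriori
    estimates of action and outcome timing under a causal prior, the
    posterior-ratio rule for causality detection, the analytic detection
    probability, and the confidence in the causal estimate (CCE) proposed as
    a quantitative measure of the feeling of agency. Includes a Monte-Carlo
    trial simulator for baseline and operant timing-judgement conditions,
    grid-search fitting of the causal-prior parameters against reported mean
    perceptual shifts, and presets reproducing classic intentional-binding
    and temporal-repulsion experiments from their published summary
    statistics alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
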