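Package: drpsig
Title: Drug Response Predictor Signatures and Survival Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multigene drug-response-predictor (DRP) signatures from a
    cell-line expression panel and GI50-derived drug sensitivities (logit
    normalization, Pearson correlation thresholding, clinical presence
    filtering), scores tumor expression profiles to a percentile scale against
    a reference population, evaluates the score against time-to-event
    endpoints with stratified Cox proportional hazards models
    (50-percentile-point hazard-ratio scaling, multivariate adjustment,
    interaction tests, dichotomized Kaplan-Meier and log-rank,
    martingale-residual diagnostics), and derives clinical cutpoints by
    solving for the DRP value at which the model-based probability of
    progression at a fixed horizon equals a target. Includes seeded
    simulators for the cell-line panel, a clinical compendium, the reference
    population and a patient cohort, so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
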