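Package: sedbayes
Title: Bayesian Hierarchical Multinomial Models for Longitudinal Sedation Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bayesian hierarchical multinomial-logit models to 6-level
    Ramsay sedation scores observed at three measurement occasions per
    patient. Implements five model variants combining constant covariate
    effects, lagged-response (transition) effects with constant or
    wave-varying coefficients, and patient-level random intercepts; an
    adaptive Metropolis-within-Gibbs sampler with per-draw deviance
    tracking; DIC and wave-restricted DIC* model comparison; posterior
    summary tables with batch-means Monte Carlo errors; and a synthetic
    cohort generator with known ground truth for parameter-recovery and
    model-discrimination experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
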