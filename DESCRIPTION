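Package: eiphlca
Title: Latent-Class Evaluation of Diagnostic Tests for Exercise-Induced
    Pulmonary Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the diagnostic accuracy of tracheobronchoscopy (TBE)
    and bronchoalveolar-lavage red-blood-cell concentration (BALFRBC) for
    exercise-induced pulmonary hemorrhage (EIPH) in horses when no gold
    standard exists.  Fits a Bayesian latent-class model in which log
    BALFRBC follows a two-component normal mixture indexed by latent EIPH
    status and the TBE outcome is Bernoulli conditional on that status,
    using an adaptive random-walk Metropolis-within-Gibbs sampler on the
    marginalized likelihood.  Provides maximum a posteriori parameter
    estimates, model-based ROC curves, F1-optimal diagnostic thresholds,
    prior-sensitivity analysis, convergence diagnostics, a synthetic cohort
    generator with the study's design structure, and the descriptive layer
    (tied-rank correlation, repeated-measures comparison of repeat lavages,
    per-score summary tables, cross-tabulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda
Config/testthat/edition: 3
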