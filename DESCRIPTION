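Package: aczpd
Title: Population Pharmacodynamics of Acetazolamide in Ventilated COPD
    Patients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Indirect-response (turnover) modelling of the respiratory
    effect of intravenous acetazolamide in mechanically ventilated COPD
    patients with metabolic alkalosis. A one-compartment drug-amount model
    drives a serum-bicarbonate turnover equation, which is chained by
    power laws to minute ventilation and then to PaCO2. The package
    provides a synthetic-cohort generator emulating the reference study
    design (68 subjects, NONMEM-style datasets), a stochastic
    approximation EM (SAEM) estimator with per-subject MCMC for the
    nonlinear mixed-effects model, importance-sampling log-likelihood,
    AIC/likelihood-ratio covariate selection, normalized prediction
    distribution error (NPDE) diagnostics with decorrelation, shrinkage
    and goodness-of-fit summaries, and a Monte-Carlo dose-regimen
    simulator for predicting the effect of high acetazolamide doses on
    minute ventilation and PaCO2.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
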