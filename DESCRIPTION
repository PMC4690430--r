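Package: healthmarkov
Title: Latent Markov Health Models and Morbidity Scenarios for Health
    Expenditure Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of a latent Markov model of health in older adults,
    combining categorical health indicators observed at multi-year survey
    waves with annually observed health care costs, using the
    expectation-maximization algorithm with forward-backward recursions that
    tolerate intermittently missing emissions. Includes a seeded synthetic
    panel generator emulating a survey-registry linkage, two-part
    (logit + Gamma) cost emission models, morbidity scenario machinery
    (expansion of morbidity, compression of morbidity, dynamic equilibrium)
    calibrated numerically to target life expectancies, deterministic
    cohort-component population projection by health state, and reporting of
    state-decomposed life expectancy, lifetime costs, and aggregate
    expenditure growth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
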