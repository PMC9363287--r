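Package: cohortsem
Title: Structural Equation Modelling of Cardiovascular Biomarker Panels
    with Synthetic Cohort Simulation
Version: 1.0.0
Authors@R:
    person("Cohortsem", "Developers", email = "maintainer@cohortsem.org",
           role = c("aut", "cre"))
Description: A self-contained maximum-likelihood engine for covariance
    structure models (confirmatory factor analysis, second-order latent
    factors and structural paths), together with a seeded generator of
    synthetic elderly-cohort biomarker data and the analysis stages of a
    selenium / coenzyme Q10 intervention study: age partial-correlation
    screening, a selenium/age exogenous quotient, CFA of a 13-biomarker
    panel, a full second-order structural model with mediation effects,
    arm-wise factor-score change tests, a cardiovascular-age regression
    and a selenium-quartile mortality test. Fit is assessed with the
    chi-square statistic, RMSEA and CFI; reliabilities use the composite
    (construct) reliability index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
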