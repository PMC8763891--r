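Package: weldfume
Title: Long-Term Metal Fume Exposure Assessment for Welders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and rating long-term occupational
    exposure to welding metal fume (Cr, Fe, Mn, Ni, Pb). Estimates fume
    emission rates from test-chamber concentration traces by a simplified
    mass-balance estimator, predicts worker exposure with the closed-form
    two-zone (near-field/far-field) dispersion model, propagates daily
    operation records through the model by Monte Carlo to build a predicted
    long-term lognormal exposure distribution, validates predictions against
    paired measurements (ordinary least squares and Spearman rank
    correlation), and performs Bayesian decision analysis on a
    geometric-mean/geometric-standard-deviation grid to produce
    exposure-rating decision charts (ER0-ER4) with action-level exceedance
    probabilities. Seeded synthetic-data generators emulate every study
    input so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
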