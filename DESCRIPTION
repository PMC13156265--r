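Package: ratlungref
Title: Reference Equations and Z-Scores for Rat Lung Function
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clinical-style reference values for respiratory mechanics and
    lung volume in laboratory rats. Implements Gaussian location-scale
    (GAMLSS-type) prediction equations for airway resistance (Raw), tissue
    damping (G), tissue elastance (H) and end-expiratory lung volume (EELV)
    as functions of body mass, strain, sex and positive end-expiratory
    pressure; z-score and percentile interpretation with normal-range
    classification; a maximum-likelihood location-scale model fitter with
    Cox-Snell R2, GAIC and residual diagnostics; synthetic rat cohort
    generation; Monte Carlo cross-validation with coverage, RMSE and MAE
    metrics; constant-phase modelling of forced-oscillation input impedance;
    and plethysmographic EELV computation from occluded-breathing pressure
    traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
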