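Package: glunefa
Title: Systemic Glucose-Insulin-NEFA Dynamics After Meals and Under Clamps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-body ordinary differential equation model of the
    postprandial interplay between plasma glucose, insulin and
    non-esterified fatty acids (NEFA). The glucose-insulin core follows the
    Dalla Man meal-simulation model and is extended with plasma NEFA
    kinetics (concentration-dependent uptake, insulin-inhibited lipolysis,
    lipoprotein-lipase spillover driven by measured triglycerides) and with
    NEFA regulation of endogenous glucose production and insulin-dependent
    glucose uptake. Includes simulation of hyperinsulinemic/hyperglycemic
    clamp protocols, multi-step insulin cascades and oral glucose/fat
    tolerance tests; weighted-least-squares multi-start calibration with
    two-stage ensemble selection; perturbation and relative-contribution
    analyses of NEFA control of postprandial glucose fluxes; and a
    synthetic-data generator emulating the structure of the clamp and meal
    calibration datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
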