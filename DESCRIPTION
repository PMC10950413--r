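Package: mgpk
Title: Two-Compartment Pharmacokinetic Prediction and Validation Analytics
    for Intravenous Magnesium Sulfate in Preeclampsia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form two-compartment intravenous-infusion
    pharmacokinetics with superposition over per-case dosing histories
    (bolus plus piecewise-constant maintenance rates), covariate
    individualization by body weight and serum creatinine, and an
    endogenous magnesium baseline.  Includes a synthetic cohort generator
    emulating the Zuspan regimen (4 g bolus, 1 g/h maintenance) with
    stepwise dose titration and a measurement-error model; an
    external-validation toolkit (time-matched prediction error with
    confidence interval, bias regression against covariates, calibration
    table, treatment-period summaries, aberrant-value and toxicity
    screening); and time-to-target event analysis (Kaplan-Meier with
    Greenwood confidence bands, quartile stratification, log-rank test)
    implemented from formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    survival,
    withr
Config/testthat/edition: 3
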