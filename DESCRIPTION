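Package: twocutoff
Title: Two-Cutoff Diagnostic Thresholds and Analytical Validation for
    High-Sensitivity Plasma Biomarker Immunoassays
Version: 0.1.0
Authors@R: person("Boulder", "Bioanalytics", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Tools for analytical and clinical validation of
    high-sensitivity digital immunoassays measuring plasma biomarkers such
    as p-Tau 217. Implements four-parameter logistic calibration with
    inverse interpolation, CLSI EP17-style limit of blank / detection /
    quantitation estimation (non-parametric LoB, Cp multiplier, precision
    profile crossing), EP05-style nested variance components, linearity and
    dilution recovery, interference and stability summaries, cross
    reactivity, and a two-cutoff clinical threshold methodology: log-normal
    group modelling, bootstrap factor ranges, maximin Latin hypercube
    space-filling designs, desirability optimization of false-positive and
    false-negative rates, and conversion of optimal rates to concentration
    cutoffs. Clinical performance summaries include sensitivity,
    specificity and accuracy excluding the intermediate (gray) zone, Wilson
    score intervals, Mann-Whitney AUC with DeLong confidence intervals,
    predictive values versus prevalence, and likelihood-ratio homogeneity
    tests. A synthetic-data module generates cohorts and bench-run tables
    with the statistical structure the analyses assume, so the full
    pipeline is testable without access to clinical specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
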