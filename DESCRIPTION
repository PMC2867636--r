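Package: llapc
Title: Hazard-Function Estimation in the Log-Linear Age-Period-Cohort Model
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates age-specific cancer hazard functions from grids of
    age-adjusted incidence rates under the multiplicative (log-linear)
    age-period-cohort model I = v_j * u_l * h(t_i). Period and cohort
    effect coefficients are estimated by inverse-variance pooled ratio
    chaining under the neighbor-cohort assumption (or supplied
    externally), observed rates are corrected for these effects with
    first-order error propagation, and the hazard function is obtained
    as the inverse-variance weighted mean across periods. Hazard curves
    for differently exposed populations sharing the same anchors are
    compared through age-specific relative hazards, an averaged relative
    hazard with outlier exclusion by standardized residuals, and weighted
    least-squares slope diagnostics. Includes a synthetic-grid generator
    with known ground truth and packaged SEER 9 lung-cancer hazard
    estimates for three geographical areas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
biocViews: Epidemiology, Survival, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
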