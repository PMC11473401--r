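Package: sweetmet
Title: Discovery of Dietary Intake Biomarkers from Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering urinary and plasma metabolite
    biomarkers of sweetened-beverage and added-sugar intake and relating them
    to adiposity. Includes a synthetic cohort generator (zero-inflated
    log-normal intakes coupled by a Gaussian copula, batch-affected feature
    intensities with left-censored missingness, planted food- and
    adiposity-associated metabolites), metabolomics preprocessing
    (consumer-conditional missingness filtering, per-batch half-minimum,
    censored-quantile and random-forest imputation, log-standardisation,
    location/scale batch correction, Gower KNN covariate imputation),
    three stability-oriented variable selectors (repeated double
    cross-validation with PLS or random forests, bagged LASSO with elbow-point
    frequency cutoffs) with a multi-method consensus rule, covariate-adjusted
    linear and random-intercept association models with Benjamini-Hochberg
    false-discovery control, and joint adiposity models with iterative
    variance-inflation-factor pruning, correlation-adjusted significance
    thresholds and an adaptive elastic-net sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    lme4,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
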