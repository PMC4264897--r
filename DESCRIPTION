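Package: condindex
Title: Body Condition Indices and Allometric Scaling for Morphometric Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates mass-length allometry by ordinary least squares and
    standardized major axis (model II) regression, including confidence
    intervals, slope heterogeneity tests, maximum-likelihood common slopes
    with likelihood-ratio tests, elevation (adjusted mean) tests and slope
    comparisons.  Computes per-individual body condition scores (the scaled
    mass index and the standardized residual index), standardizes body
    composition components (water, fat, lean dry mass) to a reference size,
    and validates indices by correlation against the components.  Compares
    condition-assessment methods (index ANOVA versus mass ANCOVA with a size
    covariate) on two-factor experimental designs, with homogeneity-of-slopes
    and homoscedasticity pre-tests.  Includes a synthetic morphometric
    population generator with a latent-condition model for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
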