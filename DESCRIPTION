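Package: bmitrend
Title: Rural and Urban Trends in Mean Body-Mass Index from Survey Summary Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates country-level trends in mean body-mass index (BMI) by
    rural and urban place of residence from heterogeneous survey summary data.
    Implements a Bayesian hierarchical model with country-specific linear
    trends, second-order random-walk smoothing, nonlinear age patterns, a
    country-year-varying urban-rural difference, and fixed and random effects
    for subnational and community data sources, fitted by a block Gibbs
    sampler. Includes cleaning rules for individual survey records, a
    regression crosswalk from BMI-category prevalences to mean BMI with full
    uncertainty propagation, age-standardization and population-weighted
    aggregation of posterior draws, a decomposition of the change in
    population mean BMI into rural-change, urban-change and urbanization
    components, held-out cross-validation designs, and a synthetic-world
    generator that emulates the statistical structure of multi-country
    survey databases for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    methods,
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
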