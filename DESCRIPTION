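Package: spousim
Title: Spousal and Random-Pair Similarity in Cardiometabolic Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify similarity in cardiometabolic risk factors
    between male-female pairs, contrasting spouse pairs with exact-age-matched
    random re-pairings. Provides a synthetic couple-cohort generator with
    configurable assortment/cohabitation structure, harmonization of raw
    measurements (body mass index, Friedewald low-density-lipoprotein
    cholesterol, medication back-adjustment, outlier exclusion, disease and
    lifestyle flags), an exact-age stratified shuffle that builds a
    covariate-matched permutation null, simple and age-residual-adjusted
    Pearson correlations with Fisher-z intervals, crude and age-adjusted
    concordance odds ratios from logistic models, and descriptive reporting
    with group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
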