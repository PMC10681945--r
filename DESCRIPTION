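Package: milksub
Title: Beverage Intake Trends and Milk Substitution Modeling for
    Survey-Weighted Dietary Recall Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design-based analysis of 24-hour dietary recall microdata in
    the NHANES/WWEIA style: classification of recalled items into beverage
    groups from WWEIA category codes, survey-weighted means and
    covariate-adjusted (least-squares) means with Taylor-linearized
    standard errors, stratum/PSU sandwich-variance trend regression across
    childhood ages, population-ratio nutrient contributions of caloric
    beverages, and two dietary substitution models (adding one cup of milk
    per day, and isocaloric replacement of nonmilk caloric beverages
    consumed at lunch and dinner with milk). Includes a synthetic
    recall-data generator with a machine-readable truth ledger so every
    estimator can be exercised and validated without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readr,
    yaml
Suggests:
    arrow,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
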