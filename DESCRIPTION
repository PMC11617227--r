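Package: bouillonfort
Title: Modeling Bouillon and Staple-Food Fortification Impacts on Dietary Micronutrient Adequacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing micronutrient adequacy from household
    consumption-and-expenditure surveys (adult-male-equivalent allocation and
    the nutrient-density method) and from replicate 24-hour dietary recalls
    (a simplified usual-intake estimator with EAR cut-point and full-probability
    prevalence), and for simulating large-scale fortification of bouillon and
    staple foods. Includes absorption sub-models for iron, zinc and vitamin B12,
    WHO-style selection of fortification levels under tolerable-upper-intake
    constraints, and a synthetic-data generator that emulates the statistical
    structure of the survey inputs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
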