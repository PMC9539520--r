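Package: phenomatch
Title: Age-Structured Phenological-Mismatch Analysis for Precocial Chicks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies phenological mismatch between precocial shorebird
    chicks and their invertebrate prey. Converts invertebrate length records
    into daily biomass and prey body-mass series with quadratic peak
    estimation and mixed-model interannual trends; fits fixed-asymptote
    logistic growth curves and body-condition indices; fits a Bayesian
    hierarchical known-fate daily-survival model with time-varying resource
    covariates, an age-by-prey-size interaction, indicator-variable model
    selection and WAIC comparison; and builds annual resource and consumer
    demand curves (peak-demand and whole-demand) whose overlap, peak-date
    difference and height are related to annual fledging rates. Includes a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nlme,
    lme4,
    mgcv,
    minpack.lm,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
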