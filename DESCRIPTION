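Package: iwle
Title: Item-Weighted Likelihood Ability Estimation for Mixed-Format Tests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Latent-ability and growth estimation for tests that mix
    dichotomous (Rasch / two-parameter logistic) and polytomous
    (partial credit) items, under both a longitudinal two-occasion
    multidimensional Rasch model for learning and change and ordinary
    unidimensional models.  Implements an item-weighted likelihood
    estimator in which each item's log-likelihood contribution is
    weighted by its share of the test information, alongside maximum
    likelihood, box-uniform maximum a posteriori, Warm's weighted
    likelihood, and type-weighted likelihood estimators.  Includes a
    seeded Monte-Carlo evaluation framework (bias, RMSE, RMSD,
    truth-estimate correlation), item-bank and response-matrix CSV
    interfaces, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
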