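Package: betabrowning
Title: Nonmonotonic Microbial Diversity Responses Along Freshwater Browning Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect nonmonotonic responses of lake bacterial
    communities to browning (increasing colored dissolved organic matter).
    Implements pairwise beta-diversity response-surface regression over
    browning descriptors with gradient-boosted trees, random forests, a
    feed-forward neural network and a polynomial baseline; ridge/valley
    ("guardrail") threshold detection on the fitted surface; MINE (maximal
    information coefficient and maximum asymmetry score) screening of
    individual taxa for non-monotonicity; alpha-diversity estimators,
    rarefaction and exact species accumulation; variance partitioning by
    redundancy analysis; and a seeded synthetic-community generator with
    known regime thresholds for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    vegan,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
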