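Package: rfsdm
Title: Random-Forest Species Distribution Modelling from Presence-Only Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for modelling species distributions with
    random forests (classification-tree and regression-tree algorithms) when
    only presence records are available. Covers collinearity pruning of an
    environmental predictor stack, pseudo-absence generation by geographic
    exclusion or surface range envelope, spatial block cross-validation,
    pairwise-distance-matched evaluation data, threshold-independent and
    threshold-dependent accuracy metrics, eight objective threshold-setting
    methods, and ensemble habitat-suitability maps. Ships a virtual-species
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
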