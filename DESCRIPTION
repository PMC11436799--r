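Package: paddygap
Title: Yield Gap Decomposition and Intervention Targeting for Rice Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics pipeline for field-level rice survey data: estimates
    attainable yields and attainable yield gaps from large-n farm surveys,
    fits random-forest yield models, decomposes yield gaps into the top
    management constraints with sequential individual conditional expectation
    (ICE) sweeps, localises constraints per field with interventional Shapley
    attributions for tree ensembles, clusters fields by nitrogen/irrigation
    co-limitation, maps spatial constraint hotspots with the Getis-Ord Gi*
    statistic, and evaluates blanket versus targeted intensification scenarios
    for production, input use, profit, and nitrogen-use efficiency. Includes a
    synthetic survey-landscape generator with recorded ground truth so every
    stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ranger,
    geosphere,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
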