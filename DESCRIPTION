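Package: flowhier
Title: Flow-Hierarchy Analysis of Urban Trip Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hierarchical organization of urban mobility from
    origin-destination trip networks. Extracts hotspot activity levels by
    iteratively thresholding the Lorenz curve of cell outflows (the Loubar
    method), builds the level-to-level trip matrix, and computes the
    flow-hierarchy metric Phi together with uniform and marginal-preserving
    null models. Includes production-constrained trip-distribution models
    (gravity with tunable mass exponent, radiation, population-weighted
    opportunities) for model-based Phi estimation, correlation and
    multivariate machinery linking Phi to per-city indicators, a synthetic
    city generator for controlled experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
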