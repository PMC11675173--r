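Package: thalroute
Title: Stochastic Routing Costs and Efficiency Metrics on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Graph-theoretic analysis of how a pivot region (typically the
    left thalamus) is embedded in weighted structural connectomes. Provides
    nodal efficiency measures (clustering coefficient, local efficiency), a
    lambda-tuned stochastic routing model with absorbing-chain transmission
    cost and Kullback-Leibler informational cost, degree-, strength- and
    weight-preserving null networks for cost normalization, pivot-centred
    cost aggregation over a reading subnetwork, and brain-behaviour
    statistics (partial correlations with permutation-based family-wise
    error correction and hierarchical regression). Includes a synthetic
    cohort generator so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
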