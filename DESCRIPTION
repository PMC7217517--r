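Package: takeover
Title: Takeover-Time Distributions for Contact Infection on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a minimal susceptible-infected contact process on
    networks (at each discrete time step a uniformly random node and one of
    its neighbors are drawn; infection spreads only from an infected node to
    a susceptible neighbor, and every step counts toward the clock) and
    provides the exact geometric-chain reductions and analytical limiting
    distributions of the takeover time: normal for rings and 2D lattices,
    Gumbel for the star graph, the convolution of two Gumbels for complete
    and dense Erdos-Renyi graphs, and an intermediate skewed family for
    d-dimensional lattices with d >= 3. Includes event-level and accelerated
    samplers, partial-takeover times, goodness-of-fit summaries
    (moments, skewness, Kolmogorov-Smirnov), hypoexponential closed forms,
    and a three-parameter lognormal density for comparison with empirical
    incubation-period fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
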