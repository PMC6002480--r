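Package: treemingle
Title: Species Mingling Analysis for Stem-Mapped Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marked point-pattern analysis of neighbourhood species mingling
    in fully mapped forest plots. Implements the nearest-neighbour mingling
    index with mingling-level distributions and pairwise tree-size rank
    tests, cumulative mark mingling functions by tree-size class with
    translation edge correction, size-class difference statistics, and
    pointwise Monte-Carlo envelopes under homogeneous and heterogeneous
    Poisson location-randomization null models. Includes simulators for
    dependent-marked two-species stands and clustered multi-species
    communities so every stage can be exercised on synthetic census data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
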