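Package: assortmate
Title: Forward Simulation of Ancestry-Assortative Mating in Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of two-way human
    admixture under explicit mate-choice models: three ancestry-similarity
    preference kernels (stationary, increasing, broad) and a two-group
    social-barrier model, all calibrated by a common endogamy strength
    parameter alpha. Local-ancestry tracts are propagated through meiosis
    with Poisson recombination on a 22-chromosome genome, and the package
    provides the downstream analyses used to study such simulations:
    mate-pair ancestry correlation over time with a permutation null,
    ancestry-variance dynamics, mating-structure summaries, and exponential
    tract-length fitting to estimate (and quantify bias in) the time since
    admixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
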