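Package: wingdiv
Title: Wing Colour Evolution, Diversification and Historical Biogeography of
    Neotropical Butterflies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-phylogenetics pipeline for colourful Neotropical
    butterfly radiations. Builds species-level wing colour traits (modal RGB
    values over homologous wing regions) from specimen images, fits Brownian
    motion models with rate shifts and mean jumps by reversible-jump MCMC with
    AICM model selection, runs the equal-splits (ES-sim) trait-dependent
    diversification test, fits constant, time-dependent and
    paleoenvironment-dependent birth-death diversification models, and
    estimates ancestral geographic ranges under time-stratified DEC and
    DIVALIKE models over an adjacency-restricted range state space. A
    synthetic-data module simulates trees, traits, range histories and wing
    images so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    Rcpp,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
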