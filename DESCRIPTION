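Package: mitoarc
Title: Microhomology and Contact-Zone Modelling of Human mtDNA Major-Arc Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spectrum of large deletions in the major
    arc of human mitochondrial DNA. Detects perfect and degraded direct and
    inverted repeats on a circular genome, builds window-pair microhomology
    matrices from affine-gap global alignment scores, fits logistic models of
    deletion presence as a function of microhomology and of proximity to a
    putative single-strand contact zone, scans for the minimum-AIC contact
    point, runs randomization tests on deletion-center dispersion, clusters
    breakpoints with a density-based algorithm, contrasts realized against
    non-realized repeats, and approximates fine-scale single-strand folding
    with nearest-neighbor DNA duplex free energies. A synthetic-data module
    generates genomes with planted repeats and deletion tables drawn from the
    logistic realization model so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
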