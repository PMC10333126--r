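Package: gamkit
Title: Multiplex Genome Architecture Mapping Analysis with the SLICE Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Genome Architecture Mapping (GAM) data:
    segregation-table processing with in-silico multiplexing of nuclear
    profiles, normalized linkage disequilibrium (D') contact matrices, the
    extended SLICE statistical model for pairwise and triplet chromatin
    interaction probabilities (slab-geometry capture probabilities,
    mean-field multiplexing, exact null tests, FDR control and
    experimental-design power calculations), distance-stratified comparison
    of GAM and Hi-C contact matrices with delta z-score tails, feature-pair
    enrichment with matched permutation backgrounds and random-forest
    ranking, contact-complexity and triplet scoring from Hi-C transitivity
    and single-cell 3D models, insulation-square TAD boundary calling for
    matrices with negative entries, and a geometric nuclear-slicing
    simulator used throughout for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics,
    fitdistrplus,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
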