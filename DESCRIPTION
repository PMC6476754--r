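Package: chplex
Title: Chloroplast Haplotype Sharing and Polymorphism in Tree Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-scale analysis of noncoding chloroplast DNA variation
    in species-rich tree plots. Collapses aligned per-genus sequences into
    haplotypes under a two-difference rule (counting substitutions, indel
    events and small inversions) with a species-diagnostic exception,
    derives per-species polymorphism calls stratified by congener presence
    and seed-dispersal syndrome, accounts for shared versus private
    haplotype incidences among congeners, and tests the resulting contrasts
    with two-sided Fisher exact tests and per-genus binomial tail scans.
    Includes a synthetic community generator with controllable incomplete
    lineage sorting and introgression regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
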