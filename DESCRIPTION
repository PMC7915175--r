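Package: repeatscape
Title: Homology-Based Repeat Annotation, Kimura Divergence Landscapes and
    BAC Synteny Net-Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for the repeat-element side of
    cytogenomic chromosome studies. Annotates target sequences (for example
    pooled BAC inserts) against a consensus transposable-element library by
    seeded Smith-Waterman local alignment, detects perfect microsatellites
    and low-complexity runs, summarises loci density (NL/Mb) and coverage
    per repeat class and family, computes Kimura two-parameter copy
    divergences and repeat-landscape histograms (including a cross-species
    mode driven by per-chromosome custom libraries with dereplication), and
    builds weighted BAC-chromosome synteny net-graphs with a
    Fruchterman-Reingold layout. A synthetic-genome generator plants
    transposable-element copies at controlled divergence, microsatellites
    and placement tables so that every stage is verifiable against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
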