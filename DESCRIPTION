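Package: spiderfx
Title: Faster-X Evolution Analysis for Social Spiders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing faster-X evolution in species with X1X2/0
    sex determination, built around the Stegodyphus social-spider system.
    Assigns genome scaffolds to the X chromosomes from flow-sorted
    sperm-pool read counts via a two-component beta mixture on the P0
    statistic with FDR-controlled thresholds; estimates lineage-specific
    dN, dS and dN/dS per chromosome class from three-species codon
    alignments with gene bootstraps and randomization tests; computes Nei
    nucleotide diversity, piX/piA paired ratios and coefficient-of-variation
    contrasts from RAD locus alignments; performs McDonald-Kreitman tests;
    provides closed-form sex-ratio and male-mutation-bias (Miyata) theory;
    and simulates recurrent founder-event demographies for X and autosomal
    compartments with a coalescent engine. Includes seed-deterministic
    synthetic-data generators for every input class so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
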