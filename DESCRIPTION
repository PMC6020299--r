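Package: luxerode
Title: Comparative Genomics of Transposon-Driven Genome Erosion in
    Bacterial Symbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing ongoing, transposon-mediated genome
    reduction in host-associated bacteria such as the luminous symbionts
    of deep-sea anglerfishes. Implements pseudogene classification from
    best-hit protein comparisons, intra-sample allele-frequency diversity
    from pileup base counts, maximum-likelihood global- versus local-clock
    model fitting with likelihood-ratio tests, an insertion-sequence
    transposase census with terminal-inverted-repeat and burst-phylogeny
    analysis, and genome-reduction summary statistics (average nucleotide
    identity, percent reduction, functional-category counts, pathway
    completeness). A seeded synthetic degraded-genome generator with full
    ground-truth records makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
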