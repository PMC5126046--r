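Package: phagehgt
Title: Detecting Phage-Mediated Horizontal Gene Transfer Between
    Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A screening-and-evidence pipeline for detecting
    bacteriophage-mediated horizontal gene transfer between endosymbiont
    (e.g. Wolbachia) genomes. Provides Nei-Gojobori (1986) synonymous and
    nonsynonymous divergence with codon-bootstrap variance, cumulative
    GC-profile compositional segmentation for genomic-island candidates,
    attachment-site (attL/attR/attB/attP) core and inverted-repeat
    detection, Dollo loss counting on a host phylogeny, Mann-Whitney
    divergence-ratio tests, qPCR standard-curve and phage:host copy-ratio
    tests, and a seeded synthetic-data generator that emulates the
    statistical structure every stage assumes, so the whole pipeline is
    testable without external downloads.
License: MIT
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
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    rtracklayer,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
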