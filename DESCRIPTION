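Package: haplocode
Title: Multi-Locus DNA Barcoding and Haplotype-Based Species Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-locus DNA barcodes in plant germplasm
    panels. Collapses per-marker sequences into haplotypes, builds composite
    identification codes that combine concatenated sequence length with the
    per-marker haplotype labels, and scores species discrimination (resolved
    accessions, species-level assignment success) at the genus, species, and
    cultivar levels. Includes Kimura two-parameter and number-of-differences
    distances with pairwise deletion, Neighbor-Joining tree estimation with
    nonparametric bootstrap support, monophyly tests, marker concatenation,
    and a hierarchical sequence simulator plus a deterministic grass-panel
    fixture generator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
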