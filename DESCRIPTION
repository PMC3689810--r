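Package: aphidpop
Title: Population Genomics of Clonal Aphid Lines and X-Chromosome Scaffold
    Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of low-coverage resequencing
    data from clonal aphid lines: consensus calling from samtools text pileups
    with quality and majority-rule filters, site-frequency-spectrum diversity
    statistics (Watterson's theta, nucleotide diversity pi, Tajima's D) and
    Hudson's Fst over annotated gene regions, and assignment of genomic
    scaffolds to the X chromosome or autosomes from brother-male consensus
    differences corrected by population diversity, classified with a
    two-component Student's-t mixture fitted by maximum likelihood. Includes a
    synthetic-data generator emulating the study design (clonal lines,
    winged/wingless brother-male pairs that share autosomes but carry
    alternate maternal X haplotypes) and a forward simulator of cyclical
    parthenogenesis with X0 male determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
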