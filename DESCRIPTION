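Package: mutppd
Title: Mutational Proteomic Peptide-Phage Display Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for mutational proteomic peptide-phage
    display (ProP-PD) screens that probe how disease-associated missense
    variants rewire short linear motif (SLiM) mediated protein interactions.
    Covers design of tiled wild-type/mutant peptide-pair libraries over
    intrinsically disordered regions (cysteine sanitisation, constrained
    reverse translation), demultiplexing and processing of amplicon
    sequencing reads into per-replicate peptide count tables, four-criterion
    confidence scoring of enriched peptides, the mutation enrichment score
    with Mann-Whitney classification of mutation-modulated domain-peptide
    interactions, motif-position classification of mutations with Grantham
    substitution distances, fluorescence-polarisation affinity analytics
    (ligand-depletion saturation fits, logistic displacement fits, IC50 to
    K_D conversion, fold-change capping and phage/affinity agreement), and
    known-interaction enrichment. A synthetic-data generator produces
    replicate selection count tables and polarisation curves with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
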