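Package: grpfam
Title: Comparative Analysis of RNA-Binding Glycine-Rich Protein Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative analysis of the
    RNA-binding glycine-rich protein (RB-GRP) gene family between related
    plant genomes. Identifies family members from domain-hit tables and a
    sliding-window glycine-content filter, classifies them into subfamilies
    IVa-IVd by domain architecture, derives chromosome placement and
    exon/intron structure from GFF3 gene models, builds neighbor-joining
    trees with Poisson correction and bootstrap support, detects tandem and
    collinear duplications from homology hits and gene ranks, estimates
    Ka/Ks under the Nei-Gojobori (1986) counting method with Jukes-Cantor
    correction, and computes relative expression from qPCR Ct tables by the
    comparative Ct (2^-ddCt) method. A seeded synthetic-data generator with
    planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
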