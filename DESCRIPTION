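Package: cpcapture
Title: Chloroplast Capture Detection from Cyto-Nuclear Phylogenetic
    Discordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving species relationships from single-copy
    nuclear genes and detecting reticulate evolution (chloroplast capture)
    from discordance between chloroplast and nuclear phylogenies. Implements
    single-copy ortholog selection by translated local search, fixed-ploidy
    SNP filtering with allele-frequency bands, IUPAC consensus CDS
    reconstruction and supermatrix concatenation, ambiguity-aware distances,
    neighbor-joining and Jukes-Cantor pruning likelihood with exhaustive
    small-topology search, nonparametric site bootstrap, quartet-concordance
    species-tree estimation, Fitch parsimony discordance statistics,
    k-nearest-neighbour capture flagging, permutation Mantel tests of
    phylogeography, and a synthetic diploid four-species data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
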