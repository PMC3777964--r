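Package: prfscan
Title: Detection and Comparative Analysis of Programmed -1 Ribosomal
    Frameshift Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and characterising programmed ribosomal
    frameshift (PRF) cassettes of the kind that expresses the long form of the
    fungal YIP3 Rab-GDI displacement factor: slippery-heptamer scanning with
    tRNA re-pairing rules (Watson-Crick, wobble and inosine pairing, tandem
    and single P-site slippage models), exhaustive stem-loop and H-type
    pseudoknot prediction with a transparent base-pair scoring scheme,
    construction of the predicted frameshift fusion protein and its molecular
    mass, structure-aware conservation analysis of aligned cassettes
    (base-pair compatibility statistics and compensatory substitutions),
    Fitch parsimony mapping of 3'-ORF presence on a species tree, and
    quantification of frameshifting efficiency from dual-reporter
    (beta-galactosidase/luciferase) assays with an exact Mann-Whitney test.
    Includes seeded generators for synthetic cassettes, ortholog families
    evolved on a tree, and reporter datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
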