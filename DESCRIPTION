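Package: syntevo
Title: Comparative Genome Structure Analysis for Closely Related Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing genome structure between closely related
    species from assemblies and annotations: orientation-aware synteny block
    inference from unique exact anchors, rearrangement counting and inversion
    calling on signed block permutations, double-cut-and-join (DCJ) distances,
    Dollo polarization of derived events onto the branches of a species tree
    with an outgroup, branch assignment of transposable-element content by
    syntenic containment, tandem and dispersed duplication detection with
    gene-overlap classification and X-chromosome enrichment statistics,
    positional tRNA orthology with anticodon-shift calls, and conserved-intron
    length comparison. Includes a forward genome evolver that plants
    structural events along a four-taxon-plus-outgroup phylogeny and records
    a machine-readable truth ledger, so every inference step can be scored
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
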