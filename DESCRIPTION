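Package: causanet
Title: Causal Gene Network Reconstruction from Genetical Genomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs directed gene regulatory networks from paired
    genome-wide genotype and expression data in a four-step divide-and-conquer
    procedure: phenotype-discriminative module discovery on a molecular
    interactome using a hybrid bonding score and a Hotelling T-squared gate;
    module-level expression quantitative trait locus (eQTL) mapping by two-stage
    sparse partial least squares regression with linkage-block reduction;
    eQTL-anchored Gaussian (BGe) Bayesian network learning over all pairs of
    modules, accumulated into a causation matrix; and assembly of the local
    causalities into one global directed network by a Beta-random-field ranking
    procedure optimized with simulated annealing. Includes a synthetic
    genetical-genomics data generator with known causal truth and concordance
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
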