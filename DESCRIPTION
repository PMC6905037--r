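Package: lavidascope
Title: Virophage Discovery, Classification and Host Prediction from Metagenome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines assembled metagenome contigs for virophage (Lavidaviridae) genomes
    using iteratively refined major-capsid-protein profile models, applies
    quality, completeness (circularity and inverted terminal repeats) and
    de-replication rules, clusters predicted proteins into virophage protein
    clusters (VpPCs), classifies high-quality genomes into clades from a
    concatenated four-core-gene phylogeny with conserved-synteny analysis, and
    predicts co-infecting giant viruses through the MIMIVIRE shared-sequence
    criterion. Ships a synthetic metagenome generator with full ground truth so
    every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    igraph,
    ape,
    phangorn,
    jsonlite,
    limma,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
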