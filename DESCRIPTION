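Package: facoloc
Title: Co-Localization, Phyletic Profiling and Expression Classification
    of Pathway Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for surveying a gene pathway
    (shipped with a 40-component Fanconi Anemia registry) across genomes:
    phyletic presence/copy-number profiling from homology-hit tables with
    Pfam domain-architecture confirmation and gene-fusion detection; a
    window-based genomic co-localization test with an analytic
    hypergeometric/binomial approximation and an authoritative label
    permutation null; TPM computation and differential-expression status
    classification; and seeded synthetic-genome generators with planted
    ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
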