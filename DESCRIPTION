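Package: funfamscan
Title: Functional-Family HMM Scanning and GO Annotation Transfer for
    Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns query protein sequences to functional families
    (FunFams) by scanning them against a library of profile hidden Markov
    models with per-family E-value inclusion thresholds, resolves a
    consistent multidomain architecture per query, transfers Gene Ontology
    annotations with frequency-based confidence scores, propagates the
    scores up the GO directed acyclic graph and merges per-domain sets
    into a nonredundant per-protein annotation set. Includes CAFA-style
    precision-recall evaluation against BLAST-like and flat-family
    baselines, and a seeded synthetic-fixture generator (toy ontologies,
    family libraries and query sets with known ground truth) so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
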