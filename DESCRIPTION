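Package: fluxrec
Title: Flux Balance Viability Prediction and Phenotype-Driven Model Reconciliation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based simulation of multi-gene interval deletion
    strains on defined media, and reconciliation of genome-scale metabolic
    models against observed growth phenotypes. Provides flux balance
    analysis (FBA) with gene-protein-reaction (GPR) knockout evaluation, a
    twelve-class taxonomy of model/media errors with greedy net-beneficial
    correction, prediction of rescue metabolites for unviable knockouts,
    SBML (Level 3 fbc and legacy Level 2 note-style) model input/output,
    and a seeded synthetic-data generator producing ground-truth genomes,
    networks, media, intervals and phenotype tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
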