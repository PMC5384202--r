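Package: mitophylo
Title: Mitochondrial DNA Phylogeography: Haplogroup Trees, Rho Dating and
    Frequency Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mitochondrial DNA phylogeography surveys: scoring of
    variants against a reference mitogenome in PhyloTree-style nomenclature,
    maximum-parsimony haplogroup tree construction with clade-defining
    motifs, motif-based haplogroup assignment of complete and partial
    sequences, rho-statistic coalescence dating with Saillard standard
    errors and pluggable molecular-clock calibrations, Bayesian-skyline
    time-axis rescaling, ordinary kriging of haplogroup frequencies onto
    geographic grids, and a seeded coalescent simulator that generates
    complete synthetic surveys with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    graphics,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
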