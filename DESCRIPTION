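Package: barcodiver
Title: DNA Barcode Library Assessment and Cryptic Diversity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing COI DNA-barcode reference libraries.
    Computes Kimura two-parameter distances under pairwise deletion and
    summarises them across taxonomic levels; performs barcode-gap and
    nearest-neighbour analysis; simulates leave-one-out specimen
    identification under the Best Match, Best Close Match and All Species
    Barcodes criteria with fixed, cumulative-error-optimised and
    density-minimum thresholds; assesses species clusters on
    neighbour-joining trees (distinct, paraphyletic, shared); detects
    deeply divergent intraspecific lineages by average-linkage clustering
    at a 2% divergence cutoff; and classifies externally supplied Barcode
    Index Number assignments against morphology-based species labels.
    Includes a seeded simulator of aligned COI-like data sets with planted
    singletons, shared haplotypes and deep lineages for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
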