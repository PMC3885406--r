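Package: utrsnv
Title: Regulatory Impact of Single-Nucleotide Variants in mRNA UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the effect of single-nucleotide variants in mRNA
    untranslated regions on local RNA secondary structure (base-pair
    probability ensembles compared over all local regions of a folding
    window, with empirical p-values and Benjamini-Hochberg correction) and
    on microRNA target sites (seed-match change detection, duplex
    hybridization energies, create/destroy/alter classification, CLIP and
    expression filters), followed by one-sided Fisher's exact enrichment of
    cancer-associated genes. Includes an exact enumeration oracle for the
    partition-function folding, a seeded synthetic-data generator with
    ground-truth ledgers, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
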