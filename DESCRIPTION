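Package: lncscout
Title: Identification, Classification and Cross-Species Conservation of
    Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A downstream analysis pipeline for long non-coding RNAs
    (lncRNAs) assembled from multi-tissue RNA-seq. Assembled transcripts
    are compared to a reference annotation with Cufflinks-style class
    codes, passed through an identification cascade (annotation match,
    mono-exonic, length, and protein-homology filters), classified by
    position relative to the nearest protein-coding gene within a 50 kb
    window, scored for tissue specificity with the tissue specificity
    index (tau) combined across replicates, correlated with their paired
    genes by Spearman rank correlation, and assessed for cross-species
    conservation through reciprocal best hits and synteny over ortholog
    groups. A seeded simulator generates complete five-species toy
    studies with a machine-readable truth ledger for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
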