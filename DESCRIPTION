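Package: coralmir
Title: Small RNA Discovery, miRNA Target Prediction and GO Enrichment for
    Coral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small-RNA analysis toolkit modelled on miRNA
    discovery studies in non-model cnidarians. Provides FASTQ quality control
    with an expected-error statistic, exact-match read mapping with a
    multi-locus discard rule, hairpin precursor excision and weighted
    Nussinov folding, bona fide miRNA classification from Dicer-geometry
    metrics (2-nt 3' overhang, 5'-end homogeneity, stem mismatches),
    conservation matching against known miRNA references, accessibility-energy
    (delta-delta-G) target prediction on 3' UTRs extracted by longest-ORF
    scanning, and decorrelated (elim) GO term enrichment. A synthetic-data
    module generates genomes with planted hairpins, read libraries with a
    piRNA-like 5'-U bias, transcripts with planted target sites, and
    ontologies with one truly enriched term, so the whole pipeline is testable
    against known truth without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
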