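Package: selseq
Title: Simulation and Analysis of Growth-Selection Sequencing Screens of
    Degenerate Promoter Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse SEL-seq style experiments, in
    which a degenerate promoter element library drives a growth-rescue
    reporter and functional variants are identified by their enrichment in
    sequencing counts after serial-dilution selection. Includes a seeded
    synthetic-data generator (biased degenerate libraries, multinomial
    sequencing with per-base error, log-normal per-cell fluorescence), a
    prototrophy-selection simulator with a pathway-deletion control strain,
    read extraction and fold-enrichment scoring with a pathway-dependence
    filter, IUPAC consensus scanning and ungapped best-match alignment
    against promoters, and reporter-assay analysis (fold induction,
    truncation-boundary localisation, scanning mutagenesis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
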