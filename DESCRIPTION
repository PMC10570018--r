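Package: mircds
Title: Duplex Prediction, Functional Classification and Hybrid-Read
    Annotation for miRNA Sites in Coding Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying microRNA targeting of protein-coding
    regions: dynamic-programming prediction of intermolecular
    miRNA:target duplexes with dot-bracket output, a rule-based
    classifier of miRNA-response-element functionality derived from
    reporter mutagenesis (seed, central, supplementary and 3'-terminal
    pairing zones), a transcriptome-wide scanner for extensively
    complementary CDS sites, a CLASH/CLEAR-CLIP hybrid-read pipeline
    (interval expansion, region annotation, duplicate collapsing,
    anchored base-pairing profile matrices), and a seeded synthetic-data
    generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
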