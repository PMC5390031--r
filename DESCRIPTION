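Package: mirseedscan
Title: Homology-Based Discovery of Seed-Expressed miRNAs and Their
    Downstream Validation Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An EST-based pipeline for homology discovery of plant
    microRNAs and the analytics used to validate them. Covers EST
    cleaning and greedy assembly, seeded homology scanning against known
    mature miRNAs, precursor extraction and hairpin folding with
    MFE/AMFE/MFEI statistics, triplet structure-sequence features with a
    trainable hairpin classifier and rule-based curation, target-site
    expectation scoring, hypergeometric enrichment with
    Benjamini-Hochberg FDR, qPCR 2^-ddCt fold changes, regional
    amplification PCR (RA-PCR) cleavage inference, HPLC linear
    calibration for isoflavone quantification, neighbor-joining
    phylogenies with bootstrap support, and synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
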