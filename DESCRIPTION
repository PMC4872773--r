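Package: lncBreadth
Title: Expression-Breadth Classification and Characterization of Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies ubiquitously expressed (UE) and tissue-specific (TS)
    long non-coding RNAs from a tissues-by-features FPKM matrix using
    background-calibrated detection thresholds, a coefficient-of-variation
    filter and the Jensen-Shannon tissue-specificity score, then
    characterizes the resulting gene classes (gene structure, sequence
    conservation, CpG-island promoters, transcription-factor and miRNA
    regulators, promoter histone-modification metaprofiles, enhancer and
    essential-gene proximity) and predicts their functions by
    guilt-by-association: neighbor co-localization plus co-expression with a
    permutation test for UE lncRNAs, and joint hierarchical clustering of
    active histone-mark promoter profiles with protein-coding genes for TS
    lncRNAs, with hypergeometric Gene Ontology enrichment. Ships a
    self-consistent synthetic-data generator with planted ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    cluster,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Classification, Epigenetics
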