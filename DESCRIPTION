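Package: smallRNAome
Title: Sex- and Tissue-Specific Small RNA-Seq Classification and
    Association Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing gonadal small RNA sequencing libraries in
    Caenorhabditis elegans. Implements adapter trimming with length
    filtering, a sequential six-compartment alignment cascade (contaminant,
    structural RNA, GFP sensor, recoded RNAi trigger, miRNA hairpins,
    genome), hierarchical small RNA classification (miRNA, piRNA, 22G and
    26G endo-siRNA) by length, first nucleotide and orientation,
    strand-separated per-gene counting, median-of-ratios normalization with
    rank-based sex-bias calling and germline versus somatic-gonad
    attribution, SNP-based discrimination of primary and secondary siRNAs
    from a recoded GFP RNAi trigger, RNAi phenotype-scoring statistics, and
    a quantile-binned 22G-RNA/mRNA association analysis. A synthetic
    reference and read simulator with ground-truth labels makes every step
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
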