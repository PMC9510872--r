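Package: anchorfill
Title: Anchor-Guided Assembly Finishing and Centromere Satellite Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for finishing telomere-to-telomere plant genome
    assemblies and analysing their centromeric satellite architecture.
    Implements anchor-guided gap filling and region replacement between a
    draft assembly and donor contigs, clone-based structural validation,
    k-mer consensus-quality (QV) and completeness estimation with the
    Phred-scaled accuracy conversion, telomere-array and novel-region
    detection, satellite monomer decomposition with multinomial-mixture
    clustering and BIC inflection model selection, and per-cluster CpG
    methylation and ChIP enrichment summaries. A seeded simulator produces
    ground-truthed genomes, degraded drafts, donors, anchors and epigenomic
    tracks so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    stringi,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
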