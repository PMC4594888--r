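Package: degradomeKit
Title: Degradome (PARE) Analysis of Uncapped mRNA Decay, miRNA Cleavage
    Targets and Hairpin Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for parallel analysis of RNA ends (PARE) degradome
    sequencing. Maps 5' signature tags to a transcriptome with multi-mapper
    splitting, builds per-position cleavage signal profiles, normalises
    degradation (RPM) and transcription (FPKM) layers, performs two-library
    differential tests and joint decay-pattern classification, computes
    decay-related sequence features (UTR lengths, GC, MFEI), identifies
    miRNA cleavage targets from degradome peaks with plant-style
    complementarity scoring, and classifies miRNA precursor processing
    modes (loop-last versus loop-first). Includes a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'decayClasses.R'
    'degradomeKit-package.R'
    'differential.R'
    'hairpinProcessing.R'
    'io.R'
    'pipeline.R'
    'quantify.R'
    'seqFeatures.R'
    'simulate.R'
    'targetFinder.R'
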