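Package: degradomiR
Title: Small RNA and Degradome Sequencing Analysis for Plant miRNA
    Discovery and Target Identification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired small-RNA-seq and degradome (PARE)
    libraries from plants. Implements 3' adapter trimming and read cleaning,
    partitioning of clean reads into annotation classes, identification of
    known miRNAs by mismatch-tolerant matching against a miRBase-style
    reference, evaluation of novel miRNA precursor candidates by hairpin
    folding and the minimal folding free energy index (MFEI), detection of
    star (p3/p5) strands and Dicer-type two-nucleotide 3' overhang duplexes,
    cross-library count normalisation with log2 fold-change calling of
    stress-responsive miRNAs, and degradome-guided target identification
    with complementarity penalty scoring, expected cleavage-site mapping,
    T-plot profiles and category I-IV cleavage classification. A seeded
    synthetic-data generator plants miRNA hairpin loci, condition-specific
    abundances and cleavage peaks so the whole pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, GeneRegulation, DifferentialExpression
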