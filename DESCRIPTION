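Package: methylwin
Title: Sliding-Window Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Context-resolved analysis of plant whole-genome bisulfite
    sequencing data: per-cytosine CG/CHG/CHH context classification,
    genome-wide and chromosomal-window methylation summaries, gene-body and
    transposable-element metaprofiles, a sliding-window differential
    methylation caller (Fisher's exact test with Benjamini-Hochberg
    correction, fold-change filtering, differentially methylated cytosine
    refinement and gap merging), assignment of differentially methylated
    regions to gene functional regions, and hypergeometric term enrichment.
    Includes a synthetic two-sample methylome generator with ground-truth
    differential regions so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics, Sequencing
RoxygenNote: 7.3.3
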