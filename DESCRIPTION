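Package: nfqc
Title: Nuclear-Fraction Quality Control for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a per-droplet nuclear fraction -- the share of aligned
    reads originating from unspliced, intronic pre-mRNA -- from cell-barcoded
    BAM files, either from aligner region tags or by overlap with a gene
    annotation. The nuclear fraction, combined with per-droplet UMI counts,
    is used to flag empty droplets (kernel-density valley thresholding) and
    damaged cells (per-cell-type two-component Gaussian mixture fitted by
    expectation maximization with BIC model selection). Includes a fully
    synthetic fixture generator (annotation, tagged BAMs, droplet
    populations with ground truth) and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    graphics,
    grDevices,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
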