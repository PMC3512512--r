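Package: nsa
Title: Reference-Free Scaling of SNP-Array Signals to DNA Copy Numbers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scales summarized allele-specific SNP-array signals to DNA copy
    numbers without control samples. Within every tumor sample the method
    detects copy-number-neutral regions without loss of heterozygosity by
    segmenting a binary track of balanced-allele (heterozygous, neutral
    copy number) calls with a circular binary segmentation variant, builds
    per-SNP references from the samples that are normal at each locus, and
    rescales across SNPs and across samples so that normal regions sit at
    two copies. An optional batch-effect-removal mode estimates nonnegative
    per-sample weights by iterated least squares and replaces the plain
    median reference with a weighted median. Includes a synthetic SNP-array
    generator with full ground truth and ROC-based evaluation utilities for
    comparing scaling strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
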