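Package: dgeqtl
Title: eQTL Mapping on RNA-seq Counts with Linear-Model and
    Differential-Expression Frameworks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTLs) from
    multi-sample RNA-seq data with two competing statistical frameworks
    and compares them. The first follows the GTEx-style recipe: TMM
    normalization, counts per million on effective library sizes, a
    rank-based inverse normal transformation, and fast additive or ANOVA
    linear-model scans. The second treats eQTL mapping as a differential
    gene expression problem: negative binomial generalized linear models
    on raw counts with TMM offsets and quasi-likelihood F-tests, a
    collection-site covariate, and a two-tier ANOVA plus pseudo-coded
    contrast procedure that classifies significant eQTLs as additive or
    dominance allelic effects. Includes the full variant QC cascade
    (depth, SNP-only, call rate, per-class counts, minor allele
    frequency, exact Hardy-Weinberg test at a false discovery rate),
    expression QC (sample depth, CPM/biotype gene filters, outlier-gene
    removal), a synthetic-data generator with known allelic effects,
    calibration/power study drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    edgeR,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
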