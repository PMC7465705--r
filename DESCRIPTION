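Package: peakforest
Title: Robust Genotype-Phenotype Association via Spline Peak Detection
    and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Six-phase framework for robust genotype-phenotype association
    in quantitative-trait GWAS. A single-SNP linear mixed model Wald scan
    (EMMAX-style, with principal-component covariates and a genomic
    relationship matrix) is followed by per-chromosome cubic smoothing
    splines fitted to the Wald statistics; concave-down regions between
    consecutive inflection points are called as peaks, and peaks whose
    height exceeds the 95th percentile of a phenotype-permutation null of
    maximum peak heights are declared QTLs. Independently, the Boruta
    random-forest wrapper classifies every SNP as Confirmed, Tentative or
    Rejected. SNPs that are Boruta-Confirmed and fall inside a QTL are
    reported as robust SNPs, with LD profiles, genotype-class phenotype
    comparisons and gene-interval annotation. Includes a synthetic-data
    generator (LD-block haplotype-pool genotypes, planted QTL effects,
    polygenic background) and multiple-testing thresholds via the
    effective number of tests (simpleM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    ranger,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
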