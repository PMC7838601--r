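Package: densityCNV
Title: Density-Peak Outlier Detection of Copy Number Variants from
    Read-Depth Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) in tumour sequencing
    samples from a binned read-depth profile. Per-bin read counts are
    loaded from a coordinate-sorted BAM file or a count table, corrected
    for GC-content bias by median-stratum scaling, and smoothed with an
    exact one-dimensional fused-lasso (total-variation) solver into
    piecewise-constant segments. Each segment is scored with two
    density-peak features, local density and minimum distance, and tested
    against a bivariate Gaussian null distribution fitted to all
    segments; significant outliers are reported as amplification or
    deletion calls relative to the cluster-centre baseline read depth.
    Includes a purity- and coverage-aware negative-binomial simulator
    with ground-truth intervals, call-set evaluation (sensitivity,
    precision, F1), and an overlapping-density-score utility for
    comparing call sets from multiple methods.
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
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: CopyNumberVariation, Sequencing, Coverage, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
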