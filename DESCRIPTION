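Package: sweepscan
Title: Selection Sweep Scans from SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Sweepscan", "Developers", role = c("aut", "cre"),
    email = "sweepscan-dev@example.org")
Description: Detection of candidate selection sweep regions in livestock
    SNP-array data. Implements quality control and LD thinning for PLINK
    PED/MAP genotypes, PCA and discriminant analysis of principal components
    (DAPC) for population structure, per-SNP Weir-Cockerham FST and the di
    differentiation statistic, extended haplotype homozygosity scans (EHH,
    iHS within a group; EHHS/iES, Rsb between groups) on phased haplotypes
    with a Gaussian tail-probability significance transform, candidate-region
    calling with cross-method intersection and local gene-interval
    annotation, and a Balding-Nichols simulator with haplotype sweep
    injection that makes every stage testable without controlled-access
    genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
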