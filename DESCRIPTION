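Package: crossLD
Title: Linkage Disequilibrium in Crossbred Populations from Haplotypes and
    Unphased Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-locus linkage disequilibrium (LD) in F1 crossbred
    populations. Computes crossbred allele frequencies and (negative)
    inbreeding coefficients, the true crossbred r-squared by the
    haplotype-covariance route and by the genotype-dosage-moment route
    (which are algebraically identical), plus D and D-prime. Provides
    sample estimators from phased haplotype data and from unphased
    genotype dosages (Rogers-Huff style correlation), a multinomial
    simulator of crossbred samples over configurable scenario grids, and
    Monte-Carlo summaries of estimator bias and precision (standard
    deviation, ratio of precision, t-tests). Includes TSV/VCF readers, a
    fixture generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
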