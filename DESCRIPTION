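Package: spaRV
Title: Summation of Partition Approach for Rare-Variant Association Tests
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-free, permutation-based region tests for rare genetic
    variants using the summation of partition approach (SPA). Implements the
    marginal association score I1, the pairwise gene-gene interaction score
    I2, the adaptive min-p combination p*, and the gene-environment score I1E
    with global and stratum-local phenotype permutation, for both dichotomous
    (case-control) and quantitative traits. Ships a synthetic simulation
    framework (independent rare SNPs under Hardy-Weinberg equilibrium,
    logistic or linear trait models with marginal, gene-gene and
    gene-environment terms, retrospective case-control sampling) and an
    experiment harness for estimating type-I error and power by replicated
    simulation, plus VCF/TSV ingestion and a command-line interface for
    region-based testing of real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
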