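Package: feralpopgen
Title: Population Genomics of Founder-Bottleneck and Admixed Cohorts from
    Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for the population-genomic characterisation
    of recently founded, admixed populations such as feral island livestock.
    Implements EM estimation of population allele frequencies from genotype
    likelihoods, probabilistic site-frequency spectra, genetic-load statistics
    by functional class (NS/S heterozygosity ratio, masked and realized load,
    RX/Y with block-jackknife confidence intervals), Weir-Cockerham
    F-statistics and Patterson f-statistics with block-jackknife standard
    errors, F4-ratio admixture-proportion estimation, KING-robust kinship and
    relationship-degree classification, genetic-offset statistics from
    gene-environment association coefficients, an EHH-based selection scan
    (iHS, Rsb) with Lindley local-score segmentation, and deterministic
    chronology conversions. A hybrid Wright-Fisher cohort simulator generates
    synthetic founder-bottleneck/admixture cohorts with per-class purifying
    selection and sequencing-likelihood noise for validation and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
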