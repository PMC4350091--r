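Package: rvburden
Title: Rare-Variant Case-Control Burden Analysis from Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for case-control rare-variant analysis
    of targeted sequencing data: genotype-likelihood based variant calling
    with EM estimation of population allele frequencies and a quality-filter
    bank (base-quality rank-sum, strand bias, depth/mapping-quality),
    single-marker logistic regression with permutation p-values, four
    gene-based rare-variant association tests (BURDEN, FRQWGT, VT, UNIQ)
    with adaptive permutation, gene-set burden aggregation with Fisher
    exact statistics and a normalized distinctive-loci ratio, and
    hypergeometric pathway enrichment with Benjamini-Hochberg FDR.
    Includes a calibrated synthetic cohort generator with full truth
    tables so the whole pipeline is testable without access to any
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
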