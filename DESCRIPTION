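Package: autogs
Title: Genomic Selection with Classical and Deep Learning Models
Version: 0.1.0
Authors@R: person("AutoGS", "Developers", email = "autogs@example.org",
    role = c("aut", "cre"))
Description: A desk-scale genomic-selection toolkit: high-confidence SNP
    feature extraction from VCF files (GATK-style hard filters and
    regulatory-window intersection with gene models), per-model genotype
    encodings (allele dosage, one-hot, square tensor, PCA), a pool of five
    classical machine-learning regressors and four convolutional
    genomic-prediction architectures plus an environment-gated variant,
    training with an 8:1:1 split and Pearson-R evaluation, F1 hybrid
    construction and optimal-parent ranking, and a synthetic
    genotype-phenotype-environment simulator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
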