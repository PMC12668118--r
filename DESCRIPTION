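Package: embgwas
Title: Multivariate GWAS of Image-Derived Embedding Phenotypes
Version: 0.1.0
Authors@R: person("embgwas", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of high-dimensional
    image-derived phenotypes. Implements contrastive alignment of feature
    embeddings to a continuous label (Rank-N-Contrast) with a desk-scale
    multilayer-perceptron encoder, embedding preprocessing (eye averaging,
    PCA, rank-based inverse normal transformation), a multivariate
    chi-squared association test with K degrees of freedom alongside a
    univariate baseline with aggregated Cauchy p-value combination,
    permutation-based calibration diagnostics, greedy LD clumping of
    independent loci, and ridge-BLUP trait-axis construction with
    leave-one-out predictions and embedding interpolation. A seeded
    synthetic cohort generator (genotypes with tunable LD, age-structured
    features, planted genetic effects, disease labels) provides a
    self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    glmnet,
    yaml,
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
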