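Package: mmselect
Title: Multimodal Feature Selection and Integration for Sparse Omics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step framework for building interpretable classifiers from
    sparsely overlapping multi-omics cohorts. Step one prioritises features
    within each data modality by resampled preranked gene-set enrichment with
    leading-edge extraction and robust rank aggregation; step two integrates
    modalities by iterative forward selection over nested cross-validated,
    class-weighted elastic nets with Platt-scaled predictions and consensus
    feature importance. Includes modality-specific preprocessing (genotype QC,
    k-nearest-neighbour imputation, Mahalanobis outlier filtering, covariate
    residualisation) and a synthetic multimodal cohort generator with planted
    pathway-level signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'enrich.R'
    'integrate-ffs.R'
    'integrate-net.R'
    'io.R'
    'mmselect-package.R'
    'preprocess.R'
    'rank.R'
    'rra.R'
    'seeds.R'
    'select.R'
    'simulate.R'
    'usage-log.R'
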