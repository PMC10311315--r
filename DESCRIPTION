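Package: attomics
Title: Group-Wise Self-Attention Networks for Omics Phenotype and Survival Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the AttOmics architecture: a high-dimensional omics profile
    is partitioned into feature groups, each group is embedded with its own
    fully connected network, multi-head self-attention is applied across the
    group embeddings, and a prediction head outputs either multi-class
    phenotype probabilities or a Cox log-risk score. Includes random,
    constrained K-means and gene-set (GMT) grouping strategies, weighted
    cross-entropy and Cox partial-likelihood losses with Adam training and
    early stopping, classification and concordance-index metrics,
    per-phenotype attention-map interpretation, and seeded synthetic data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    clue,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    survival,
    pheatmap,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'attention.R'
    'grouping.R'
    'io.R'
    'losses.R'
    'metrics.R'
    'model-backward.R'
    'model-build.R'
    'model-forward.R'
    'pipeline.R'
    'synthetic.R'
    'train.R'
    'utils.R'
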