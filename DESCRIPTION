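Package: vnnomics
Title: Visible Neural Networks for Multi-Omics Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains biologically masked ("visible") neural
    networks that predict phenotypes from DNA methylation and gene
    expression. Network connectivity is derived from genomic annotation:
    CpG sites connect to their nearest gene, per-gene methylation and
    expression nodes merge into combined gene representations, and genes
    optionally feed a three-level pathway hierarchy with skip connections
    for unannotated genes. Includes cohort-wise cross-validation with
    hyperparameter search and seed replication, omic-specific L1
    penalties, normalized absolute-weight path-product contribution
    scores for inputs, genes, omics and pathways, activation-pattern
    principal component analysis, and a multi-cohort synthetic data
    generator with planted causal genes for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
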