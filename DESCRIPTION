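Package: triadnet
Title: Pathway-Constrained Multimodal Neural Classification of Alzheimer's Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and trains a biologically constrained, triple-input neural
    classifier that predicts cognitively normal (CN), mild cognitive impairment
    (MCI) and Alzheimer's disease (AD) status from gene-aggregated genotypes,
    gene expression and clinical features. Gene-to-pathway and
    pathway-to-pathway connectivity from a hierarchical pathway resource is
    frozen into binary masks, so the two omics subnetworks are sparse and
    non-trainable while a small fusion head learns the classification. Includes
    the full preprocessing chain (additive SNP encoding, k-nearest-neighbour
    imputation, stratified splitting, SMOTE balancing, min-max scaling),
    permutation Shapley attributions with per-modality feature ranking,
    intermediate pathway-node activation analysis via Kruskal-Wallis tests,
    cohort summary statistics, and a synthetic multimodal cohort generator with
    perturbation-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
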