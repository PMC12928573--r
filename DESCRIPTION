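Package: crossddi
Title: Cross-View Contrastive Learning for Drug-Drug Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary drug-drug interactions from chemical structure by
    encoding each drug in two complementary views: a set of BRICS pharmacophore
    subgraphs processed by a multi-head self-attention encoder, and the raw
    SMILES token sequence processed by a BERT-style sequence encoder. The two
    views are aligned with a cross-view contrastive loss, fused by
    cross-attention, and scored by a sigmoid multi-layer perceptron. Includes
    the full evaluation protocol (stratified warm-start cross-validation,
    drug-disjoint cold-start splits with per-split negative sampling, confusion
    metrics, AUROC/AUPRC, Kruskal-Wallis/Mann-Whitney/Holm model comparison,
    ablation runner) and a synthetic molecule/interaction generator with a
    plantable substructure-pair signal so the whole pipeline is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
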