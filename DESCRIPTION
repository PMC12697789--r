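Package: setperturb
Title: Permutation-Invariant Set Embeddings for Directional Transcriptomic
    Effect Prediction of Compound Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts directional (up / down / no-change), cell-specific,
    genome-wide transcriptomic intervention effects of multi-compound mixtures
    such as natural products. A mixture is modelled as an unordered set of
    compound feature vectors; a permutation-invariant set-embedding core
    (Deep Sets followed by Set Transformer attention blocks) is fused with gene
    and cell-state features, refined by self-attention, and classified by a
    three-layer perceptron. Training follows a transfer protocol: pre-training
    on abundant single-compound perturbation labels and fine-tuning on scarce
    mixture labels. Includes frozen deterministic featurizers for compounds
    (substructure fingerprint plus graph-hash embedding), genes (network and
    sequence embeddings) and cell lines (variational autoencoder), a toy
    adversarial landmark-to-genome profile enhancer, differential-expression
    labeling utilities, classical baselines, a synthetic-data generator with
    permutation-invariant ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    caret,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
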