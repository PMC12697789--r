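---
title: "Predicting directional transcriptomic effects of compound mixtures with permutation-invariant set embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting directional transcriptomic effects of compound mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setperturb)
```

## The problem

A natural product or any multi-drug preparation is a *mixture*: an unordered
collection of compounds whose joint effect on a cell's transcriptome we want
to predict gene by gene, as one of three directional classes — up-regulated,
down-regulated, or no significant change. Two properties of this problem
shape the model in this package:

1. **Permutation invariance.** The members of a mixture have no order, so
   the prediction must be a function of the *multiset* of compounds.
2. **Data asymmetry.** Single-compound perturbation corpora are enormous;
   mixture perturbation data are scarce. A model should therefore be
   pre-trained on singleton (single-compound) associations and fine-tuned on
   mixture associations — a transfer-learning protocol.

## Model

Each association is a triple (compound set $S$, gene $g$, cell line $l$)
with a class label. Frozen featurizers supply the inputs:

* **Compounds** — a 1181-component vector per compound: an 881-bit binary
  substructure-key fingerprint concatenated with a 300-component dense graph
  embedding. The graph encoder is pluggable; the built-in fallback hashes the
  molecule's atom-pair descriptor multiset, so any SMILES writing of one
  molecule maps to one vector.
* **Genes** — a 256-component network embedding of the protein–protein
  interaction graph plus a 768-component protein-sequence embedding
  (1024 total). The network embedder is a deterministic adjacency spectral
  embedding; the sequence embedder is a signed 3-mer hash. Both stand behind
  pluggable interfaces so pretrained encoders can be substituted.
* **Cell lines** — the 64-dimensional posterior mean of a variational
  autoencoder trained on expression profiles, with loss
  $$\mathcal{L} = \frac{1}{N}\sum_i \lVert x_i-\hat{x}_i\rVert^2 +
  \frac{\beta}{2}\sum_j\left(\sigma_{ij}^2+\mu_{ij}^2-\log \sigma_{ij}^2-1\right),$$
  the Kullback–Leibler term averaged over the batch to match the $1/N$
  normalization of the reconstruction term. Using the posterior mean (not a
  sample) makes the frozen embedding deterministic.

The core is the **set-embedding module**. An element network $\phi$ maps
each member's features to $d$ dimensions; the *shallow* branch is Deep Sets,
$\rho(\mathrm{pool}_i\,\phi(x_i))$, and the *deep* branch feeds
$\{\phi(x_i)\}$ through a Set Transformer stack — two induced set attention
blocks (ISAB), pooling by multihead attention (PMA, one seed), and a
feed-forward layer. Two fusion variants combine the branches:
$$\mathrm{Set}_{\mathrm{Concat}} = \mathrm{concat}\big(\mathrm{DeepSets}(x),\ \mathrm{SetTransformer}(\mathrm{DeepSets}(x))\big), \qquad
\mathrm{Set}_{\mathrm{Add}} = \mathrm{DeepSets}(x) + \mathrm{SetTransformer}(\mathrm{DeepSets}(x)).$$

The fused set vector, the two gene features and the cell feature are
projected into four tokens of a shared dimension, refined by one
self-attention block with residual layer normalization, flattened, and
classified by a three-layer MLP with strictly decreasing hidden widths
(defaults 512, 128, 32) into three logits. The signed ranking score of a
directional prediction is the softmax probability of the predicted class,
negated for down-regulation; gene lists filtered at confidence thresholds 0,
0.7 and 0.9 are exported in `.rnk` form for enrichment tools.

### Design choices in the set core

Several details were genuinely open and are worth recording:

* **Exact invariance by canonical ordering.** Floating-point addition is not
  associative, so "permutation invariance" of a pooled network is usually
  only approximate. The core instead sorts set elements into a canonical
  order (primary key: feature-row sums; exact lexicographic fallback on
  ties) before any reduction, which makes invariance *bitwise*: every
  permutation of a set yields the identical prediction.
* **Pooling.** Mean pooling is the default: mixture cardinalities span two
  orders of magnitude in real compositions and mean pooling keeps
  activations scale-stable. Sum pooling is available by configuration.
* **Batching without padding.** Variable-cardinality batching is handled by
  running each distinct set unpadded inside one computation graph and
  gathering record-level rows by set index; weights are shared across the
  per-set subgraphs. This avoids padding and masking entirely — masked
  positions cannot influence outputs because they never exist.

### Numerical core

No deep-learning framework is assumed: all trained components run on a
small reverse-mode automatic-differentiation engine over dense matrices
included in the package (tape-based, deterministic evaluation order,
Adam optimizer with weight decay). Its gradients are tested against central
finite differences through composite graphs covering every operation
family, and the attention blocks are additionally tested against a
hand-coded loop-level oracle.

## Labeling

Differential-expression statistics map to classes by the fixed rule:
class 0 (up) if $\log_2\mathrm{FC} > 0$ and $p < 0.05$; class 1 (down) if
$\log_2\mathrm{FC} < 0$ and $p < 0.05$; class 2 (no effect) if $p > 0.05$.
The rule as printed leaves $p = 0.05$ exactly, and a zero fold change with
small $p$, undefined; both are conservatively assigned to class 2 ("no
call"). For synthetic and toy data the package provides a plain per-gene
Welch two-sample test (`simple_de()`); it is not a substitute for a
moderated DE model on real counts. Raw p-values are used, matching the
stated thresholds; no multiplicity correction is applied before labeling.

## The synthetic world

Because the real corpora are far beyond desk scale, every pipeline stage is
exercised on generated worlds with known, exactly permutation-invariant
ground truth. A world draws rank-$r$ latent factors for compounds, genes
and cells (entries $N(0, r^{-1/6})$, so singleton effects have unit
variance); the effect of compound $c$ on gene $g$ in cell $l$ is
$e_{cgl} = \langle \mathrm{cf}_c \odot \mathrm{lf}_l, \mathrm{gf}_g\rangle$,
and a set $S$ acts as
$$\tanh\Big(\sum_{i\in S} e_{igl} + \gamma \sum_{i<j}
\langle \mathrm{cf}_i,\mathrm{cf}_j\rangle\,
\mathrm{sign}(e_{igl}+e_{jgl})\Big).$$
The $\tanh$ saturation makes mixture effects deliberately sub-additive:
total effect must not scale linearly with cardinality, consistent with the
observation that mixture expression changes do not correlate with compound
count. Replicate observations add Gaussian noise (`noise_sd`, default 0.3
on the log2 scale, three replicates per arm against matched controls), run
through `simple_de()` and the labeling rule. The default reference world
has 60 compounds, 200 genes, 4 cells and rank 6; the interaction strength
default is $\gamma = 0.2$, at which pairwise interactions are a minority
but non-negligible share of the pre-saturation variance.

Feature files are emitted by fixed seeded random projections of the latent
factors into the encoder-contract dimensions (881 binarized + 300 dense;
256 + 768; 64), which keeps the latent structure linearly recoverable —
tested by a probe regression — so learning is possible in principle and
failures are attributable to the model, not the features.

What the generator does *not* emulate: realistic chemistry, count-based
expression distributions, dose, batch effects, or correlated replicate
noise. Passing the synthetic experiments therefore demonstrates that the
architecture and protocol behave as designed, not that real-corpus accuracy
would be reproduced.

## Experiments and their problem sizes

`transfer_experiment()` runs the full design for one seed on the reference
world: tables subsample 40 genes, 36 singleton sets and 36 multisets of
2–6 compounds (three replicates per arm), and the mixture records are split
75/25 into fine-tuning train and held-out test partitions. The model width
is reduced to `d_set = 64`, 2 heads, 4 inducing points, one ISAB block,
fusion dimension 64 and head widths (128, 64, 32); pre-training runs 10
epochs at learning rate 3e-3 (batch 1024, L2 1e-5, dropout 0.1) and
fine-tuning 8 epochs at 1e-3. The fine-tune-only arm trains from random
initialization under the identical fine-tuning configuration — the
cleanest causal contrast (same fine-tune, different initialization) and
the literal reading of a model "trained only on the fine-tuning data". The
NoSet ablation (mean compound features in place of the set core) and the
vanilla MLP (prediction module alone on raw concatenated features) are
trained under the identical protocol. The score/effect correlation is
computed over all mixture records: it characterizes the ranking mechanism,
not generalization. These sizes are chosen so the five-seed suite
completes in roughly ten minutes on a single CPU while leaving each
ordering (transfer benefit, set-module benefit, fraction monotonicity,
threshold-correlation growth) testable; medians over seeds 0–4 are the
reported statistics. At this scale the orderings are noise-fragile:
per-seed inspection shows each holding on some seeds and not others, and
the limitations section records which median orderings do not hold under
the final protocol.

Training-parameter choices (learning rates, batch size, epochs,
regularization) were fixed by a preliminary grid search at these problem
sizes, mirroring the per-version grid-search protocol of the reference
training regimen; `grid_search_train()` exposes the same machinery to
users.

## The profile enhancer

The landmark-to-genome enhancement stage is implemented at configurable
toy dimension: a CycleGAN-style pair of generators and least-squares
discriminators with cycle-consistency weight $\lambda$, followed by a
single-hidden-layer extrapolator from the 978-gene landmark space to the
23614-gene genome-wide space. The adversarial objective is implemented
exactly as printed,
$\mathbb{E}[D(y)^2] + \mathbb{E}[(1-D(G(x)))^2]$ — note this is the
label-flipped form of the usual least-squares convention (real $\to$ 0,
fake $\to$ 1); a configuration switch selects the standard convention.
Since only the adversarial term of the "modified" scheme is printed, the
implementation is a vanilla CycleGAN with configurable cycle weight.

## Known limitations

* Compound proportions (mass ratios) within a mixture are not modeled;
  sets are unweighted, matching the stated scope.
* Quantitative fold-change regression is out of scope; the signed score is
  a ranking statistic, validated only by its correlation with the true
  continuous effect.
* The classical baselines operate on a PCA reduction of the concatenated
  features because the synthetic features are low-rank by construction and
  unreduced LDA is singular; this is applied identically to KNN, LDA and
  the decision tree.
* Absolute synthetic-suite metrics are far below what corpus-scale training
  can reach and are not comparable to such figures; only the qualitative
  orderings are meaningful at desk scale.
* **Small-sample behavior of the set core.** On the reference suite the
  NoSet ablation (fusion attention and head on the mean member features)
  reaches a slightly higher median held-out AUC than the full set model.
  Diagnostics attribute this to data efficiency, not modeling: the full
  model underfits relative to the ablation (lower training AUC, equal
  zero-shot transfer, the gap opening during fine-tuning); exploratory
  variants that made the ablation a strict submodel of the full model
  narrowed but did not close the gap at a few thousand fine-tuning
  records, while distorting the transfer orderings, and were therefore not
  kept. Attention-based set encoders should be expected to overtake
  mean-pooling only with substantially larger mixture corpora; the suite
  reports both numbers so the regime is visible rather than hidden.
* **Fragile orderings at desk scale.** Under the final protocol the
  transfer orderings (pre-train + fine-tune above fine-tune-only above
  pre-train-only) hold at the five-seed median, but the fine-tune-fraction
  curve can dip below the zero-fraction point at 25% — a small fine-tuning
  subset can disturb pretrained representations before enough data
  re-stabilizes them — and the score/effect correlation, clearly positive
  at threshold 0, is not defined at threshold 0.9 because lightly trained
  models never reach that softmax confidence (and at 0.7 it is defined only
  on seeds whose models produce enough confident calls). These are
  reported as computed rather than smoothed over.
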