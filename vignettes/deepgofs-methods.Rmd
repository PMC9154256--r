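---
title: "Learning functional similarity of genes from GO annotations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning functional similarity of genes from GO annotations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Functional similarity (FS) of two genes is classically estimated by combining
pairwise semantic similarities of their Gene Ontology (GO) annotations with a
hand-chosen aggregation metric (maximum, average, best-match average). The
choice of metric is arbitrary, differs between studies, and is decoupled from
the biological task the scores are used for. `deepgofs` instead *learns* the
aggregation: a paired neural network consumes the raw annotation sets of the
two genes and is trained end-to-end against task labels — interaction /
no-interaction for protein–protein interaction (PPI) data, log-reciprocal or
relative-reciprocal BLAST bitscores for sequence homology, or Fisher-z
transformed absolute co-expression correlations. Low-dimensional embeddings
of GO terms and of gene products fall out of the training as by-products.

# The paired network

Each gene is described, per sub-ontology channel (BP, CC, MF), by the indices
of its annotated GO terms, padded with the reserved index 0 to the corpus-wide
fixed length $t_0$ (the largest annotation set observed). The network applies
to *both* genes of a pair the same weight-shared leg — the Siamese contract
that makes the two gene representations comparable:

1. **Embedding lookup.** Index $i > 0$ maps to row $i$ of a trainable
   $V \times 100$ lookup table (one table per channel, shared by both legs);
   index 0 maps to a constant padding vector filled with $-10^9$. The result
   for a gene is a $100 \times t_0$ matrix
   $X^{\mathrm{emb}} = [x_1, \dots, x_{t_0}]$.
2. **Max-pooling.** Component $j$ of the pooled vector is
   $\max_l X^{\mathrm{emb}}_{j l}$. Because the padding value is far below any
   attainable embedding component, padding columns never win while at least
   one real annotation exists — the estimate depends only on the actual
   annotations, and is invariant to their order and to the choice of $t_0$.
3. **Channel merge and gene dense layer.** A multi-channel network
   concatenates the three pooled vectors (width 300); the single-channel
   network keeps its one pooled vector (width 100). A dense ReLU layer
   $h = \mathrm{ReLU}(W_h x + b_h)$ of equal width produces the learned
   gene-product embedding.
4. **Pair merge and highway layer.** The two gene representations are
   concatenated (width 200 or 600) and passed through a highway layer
   $$x' = \sigma(W_H x + b_H) \odot T + x \odot (1 - T), \qquad
     T = \sigma(W_T x + b_T),$$
   whose sigmoid transform gate $T$ learns, per component, how much of the
   shared information to transform and how much to carry through — replacing
   the hand-engineered aggregation metric. The layer keeps its input width,
   and as the gate saturates it degenerates to the identity ($T\to0$) or to a
   plain sigmoid layer ($T\to1$); the test suite verifies both limits.
5. **Post-highway dense and head.** A dense ReLU layer maps back to
   $d_2 = 100$ (single-channel) or $300$ (multi-channel), and a single output
   unit with sigmoid activation (classification; the score is the interaction
   probability) or linear activation (regression) produces the FS estimate.

Dropout at rate 0.3 is applied at training time after the gene dense layer,
the highway layer and the post-highway dense layer.

**Symmetry.** The pair-level weights act on a concatenation, so the raw score
is not symmetric in gene order. Training therefore sees every pair in both
orders (the instance count the optimizer sees is twice the pair count), and
prediction averages the two orders, making the reported score exactly
order-invariant.

# Definition-based embedding pretraining

Lookup tables can start from random uniform values or from embeddings
pretrained on the terms' natural-language definitions:

1. tokenize each definition into lower-cased content words (stopwords and
   single characters removed);
2. build the first-order term-by-word count matrix;
3. replace every word by its corpus-wide co-occurrence profile from a bigram
   table and sum the profiles weighted by definition counts (second-order
   expansion — this densifies the very sparse first-order vectors);
4. weight by positive pointwise mutual information,
   $\max(0, \log \frac{p(t,w)}{p(t)p(w)})$, with probabilities estimated from
   the matrix mass;
5. reduce to 100 dimensions by truncated SVD (latent semantic analysis),
   term vector = left singular vectors scaled by singular values;
6. L2-normalize rows, so cosine similarity is a plain dot product.

Numerical conventions: natural logarithm throughout (any base rescales PMI
uniformly and cosine is scale-invariant); negative PMI clipped to zero (the
standard remedy for log-of-zero and noisy negative associations); a
deterministic SVD sign convention (the largest-magnitude component of every
right singular vector is made positive) so pretraining is reproducible;
words absent from the co-occurrence vocabulary are skipped rather than mapped
to an unknown bucket, to avoid fabricating co-occurrence mass. The output
dimension defaults to 100 to match the network's lookup tables.

# Benchmark dataset construction

* **PPI.** Positive interactions are complemented by an equal number of
  negatives sampled uniformly, without replacement and seeded, from the
  unordered gene pairs absent from the positive list in either orientation;
  genes without GO annotations are removed before sampling.
* **Sequence homology.** BLAST bitscores are directional, so a pair is
  retained only when hits are reported in both directions, and the two scores
  are combined as $\mathrm{LRBS} = \log\frac{b_{AB}+b_{BA}}{2}$ or
  $\mathrm{RRBS} = \log\frac{b_{AB}+b_{BA}}{b_{AA}+b_{BB}}$ (natural log;
  RRBS of identical sequences is 0). Pairs with a gene lacking annotations in
  any sub-ontology are dropped.
* **Co-expression.** Targets are $\operatorname{atanh}(|r|)$ of the Pearson
  correlation across conditions (|r| clipped at $1 - 10^{-7}$ to stay
  finite). Because near-zero correlations dominate all-pairs sets, pairs are
  binned by $|r|$ into five width-0.2 bins (half-open, the last closed at 1)
  and an equal number is sampled from each bin.

# Evaluation protocol: gene-grouped cross-validation

Random pair-level splits leak: a gene seen in training pairs makes its test
pairs easy. The protocol therefore splits *genes*, not pairs: genes are
shuffled into $k$ near-equal chunks; the test pairs of fold $f$ are all pairs
with at least one gene in chunk $f$, and the training pairs are those with no
gene in chunk $f$. Pairs straddling two chunks are test-only in both folds.
This reading ("at least one held-out endpoint") is the only one under which
every pair is tested within one permutation — the stricter both-endpoints
rule, available as `test_rule = "both"`, leaves cross-chunk pairs untested.
Within each fold, 10% of the training pairs form a validation split that
selects the early-stopping epoch; with `refit = TRUE` the final model is then
retrained on the full training set for the selected number of epochs (the
protocol we recommend for classification, where the validation split is small
and the extra 10% of data measurably helps). The experiment is repeated over
several gene permutations and the reported value is the mean over all
permutation × fold runs.

# Optimization

Training minimizes binary cross-entropy (classification) or mean squared
error (regression) with the Adam optimizer (step size $10^{-3}$ by default,
batch size 256, optional decoupled weight decay; early stopping monitors
validation loss by default, with a validation-error-rate alternative exposed
as `monitor = "val_accuracy"`). Regression targets are
z-scored internally — otherwise the single linear output unit spends most of
training crawling toward the target mean — and predictions are mapped back to
the original scale. Early stopping monitors validation loss with patience 5
(by default) and the best-validation weights are kept.

The lookup tables are parameters of the model and are updated with everything
else, but at a reduced step size: `embedding_lr_scale` (default 0.1)
multiplies their learning rate, the usual discriminative-fine-tuning practice
for pretrained layers. The choice matters at small sample sizes: with a few
thousand training pairs, freely fine-tuned per-term vectors memorize the
training genes and generalization to held-out genes collapses, while gently
updated (or frozen, via `freeze_embeddings`) pretrained embeddings retain the
structure that transfers. In the desk-scale validation experiments below we
use 0.02 for regression and 0.002 for classification, where the binary,
1-bit-per-pair supervision overfits embeddings fastest.

The training loop is implemented twice: a compiled RcppArmadillo core (the
default engine) and a pure-R reference path. The test suite verifies that
both produce identical losses and predictions on deterministic settings, and
that the analytic gradients of every parameter tensor match finite
differences.

# The synthetic world

All validation runs on a fully synthetic stand-in for the external resources
(GO release, GAF annotations, literature bigram counts, task labels) with
known latent structure. Terms belong to latent topics; each topic has a unit
center vector and term vectors are unit-normalized perturbations of their
center (perturbation norm `jitter` = 0.5, giving within-topic cosines around
0.9 and near-zero between topics). Definitions are bags of topic-specific
words plus shared filler; the co-occurrence table is accumulated from
simulated topic-coherent documents; each gene has a primary topic and samples
80% of its annotations from it. The noiseless FS of two genes is the
symmetrized best-match average of latent term cosines — the structure the
network is meant to learn — and task targets derive from it: a balanced
median split with independent label flips (PPI), an affine transform plus
Gaussian noise (homology), or Fisher-z plus Gaussian noise (co-expression).

What the world emulates: the pipeline's file dialects (OBO, GAF, bigram
TSV), evidence-code plumbing, topic-clustered definition language, and a
learnable latent FS with controllable noise. What it does not emulate: the
scale-free topology and depth of the real GO DAG, realistic annotation-depth
biases, BLAST score distributions, or literature-scale vocabulary. Passing
the recovery experiments therefore demonstrates that the implementation
learns the structure it claims to learn at desk scale — not that it matches
published benchmark numbers on STRING, UniProt or GTEx data, which require
the original resources and GPU-scale training.

The validation experiments use a world of 300 terms per namespace, 6 topics,
500 genes, and 3000 labeled pairs with noise 0.1 (regression) or 5% label
flips (classification), evaluated by 5-fold gene-grouped cross-validation —
sizes chosen so the full suite trains some forty networks in a few minutes
on one core while leaving clear headroom above the recovery thresholds
(Spearman ≥ 0.70, F1 ≥ 0.85).

# Design choices where the design was open

* **Classification head.** A two-class softmax and a single sigmoid unit are
  mathematically equivalent for binary labels; the single unit is
  implemented, and its output is read directly as the FS probability
  (decision threshold 0.5).
* **Ancestor lifting** (`lift_annotations`) traverses only `is_a` edges;
  `part_of` and other relations are ignored as the simplest defensible
  reading of "parents". Roots map to themselves, so lifting is idempotent on
  root-only corpora and two single-level lifts equal one two-level lift on
  trees.
* **Encoded annotation order** is ascending index — any deterministic order
  works because max-pooling is order-free; ascending is reproducible.
* **Padding sentinel** is a non-trainable constant $-10^9$, below any
  realistic embedding value, so suppression under max is guaranteed.
* **Genes with partial annotation coverage** are kept for single-channel work
  on the covered sub-ontologies and excluded (strict mode) from multi-channel
  runs.
* **Best-validation weights vs refit.** By default the model keeps the
  weights of its best validation epoch; `refit = TRUE` switches to the
  select-then-retrain-on-everything protocol. We use refit for
  classification experiments (see above) and plain early stopping elsewhere.

# Known limitations

* The desk-scale experiments use a single noise knob per task; real
  annotation error is structured (evidence-code dependent, gene-family
  correlated) and is not modeled.
* The co-occurrence reader loads the full bigram matrix densely during PMI;
  literature-scale vocabularies (10^6 words) would need a streaming
  implementation.
* `run_experiment` trains folds sequentially; there is no parallelism.
* Checkpointing stores models with `saveRDS`; no cross-language format is
  provided.

# A minimal end-to-end run

```{r, eval = FALSE}
library(deepgofs)

world <- generate_world(seed = 1)
corpus <- world_corpus(world)
embeddings <- pretrain_embeddings(world$ontology, world$cooccurrence,
  dimension = 100, namespace = "BP")

pairs <- make_task_data(world, "homology", n_pairs = 3000,
  noise_sigma = 0.1, seed = 2)
config <- network_config(channels = "BP", task = "regression",
  learning_rate = 2e-3, embedding_lr_scale = 0.02,
  max_epochs = 60, patience = 8)

report <- run_experiment(pairs, corpus, config, init = embeddings,
  k = 5, permutations = 1, seed = 3)
glance(report)
autoplot(report)
```
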