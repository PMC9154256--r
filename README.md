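# deepgofs

Deep learning of gene functional similarity (FS) from Gene Ontology (GO)
annotations.

Classical GO-based FS measures score a gene pair by combining pairwise
semantic similarities of their annotation sets with a hand-picked aggregation
metric (MAX, average, best-match average) — a choice that is arbitrary and
disconnected from the biological task. `deepgofs` replaces the hand-picked
metric with a *paired (Siamese) neural network* that is trained end-to-end
against task labels and learns both the aggregation and low-dimensional
embeddings of GO terms and gene products along the way.

For a gene pair $(g_1, g_2)$ the network computes, with identical
(weight-shared) legs per gene and per sub-ontology channel (BP/CC/MF):

```
indices --lookup--> X_emb (100 x t0) --max-pool--> 100 (or 300 concat)
        --dense ReLU--> gene embedding h_i
[h_1, h_2] --highway--> x' = sigmoid(W_H x + b_H) * T + x * (1 - T),
                        T = sigmoid(W_T x + b_T)
        --dense ReLU--> d2 --sigmoid / linear--> FS(g_1, g_2)
```

Annotation lists are padded to a fixed length `t0` with a large-negative
sentinel that max-pooling suppresses; the sigmoid transform gate `T` of the
highway layer learns how the shared information of the two genes is
aggregated. Training sees every pair in both orders and prediction averages
the two, so reported scores are exactly symmetric. Lookup tables can be
initialized from definition-based embeddings pretrained with second-order
word features, positive pointwise mutual information and latent semantic
analysis (truncated SVD).

The package also provides:

* OBO / GAF parsers with evidence-code filtering (IEA+/IEA−, ND and
  NOT-qualified rows dropped) and `is_a` ancestor lifting;
* builders for the three benchmark tasks — balanced PPI classification,
  sequence-homology regression on log-reciprocal / relative-reciprocal BLAST
  bitscores (`lrbs()`, `rrbs()`), and bin-balanced Fisher-z co-expression
  targets;
* gene-grouped k-fold cross-validation that guarantees no training pair
  shares a gene with the held-out set, with repeated-permutation averaging;
* a fully synthetic world (ontology, definitions, bigram counts, annotations,
  task labels with known latent structure) so the entire pipeline can be
  exercised and validated without any downloads.

## Worked example

Everything below runs offline on the synthetic world:

```r
library(deepgofs)

world   <- generate_world(seed = 1)          # 300 terms/namespace, 6 topics, 500 genes
corpus  <- world_corpus(world)
emb     <- pretrain_embeddings(world$ontology, world$cooccurrence,
                               dimension = 100, namespace = "BP")

# nearest neighbours of a term are its topic mates
nearest_terms(emb, rownames(emb$vectors)[5], k = 3)
#> # A tibble: 3 x 2
#>   term_id    cosine
#>   <chr>       <dbl>
#> 1 GO:0000215  0.996
#> 2 GO:0000249  0.996
#> 3 GO:0000244  0.995

pairs  <- make_task_data(world, "homology", n_pairs = 3000,
                         noise_sigma = 0.1, seed = 2)
config <- network_config(channels = "BP", task = "regression",
                         learning_rate = 2e-3, embedding_lr_scale = 0.02,
                         max_epochs = 60, patience = 8)
report <- run_experiment(pairs, corpus, config, init = emb,
                         k = 5, permutations = 1, seed = 3)
glance(report)
#> # A tibble: 1 x 6
#>   task       n_runs     k permutations pearson spearman
#>   <chr>       <int> <dbl>        <dbl>   <dbl>    <dbl>
#> 1 regression      5     5            1   0.917    0.914
```

The Spearman value is the mean over the five gene-grouped folds of the rank
correlation between predicted FS and the noisy latent-similarity targets of
held-out gene pairs — genes the network never saw during training. `tidy()`
returns the per-fold values, `autoplot()` draws them.

## Command-line interface

A thin wrapper over the package functions lives at `inst/cli/deepgofs`
(installed under `system.file("cli", "deepgofs", package = "deepgofs")`):

```sh
deepgofs simulate  --out world/ --seed 1
deepgofs godata    --obo world/world.obo --gaf world/world.gaf --out corpus/
deepgofs pretrain  --obo world/world.obo --bigrams world/bigrams.tsv --out emb.tsv
deepgofs neighbors --table emb.tsv --term GO:0000005 -k 5
```
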