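# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the recovery-experiment world: 300 terms/namespace, 6 topics, 500 genes
recovery_world <- function() cached("world", generate_world(seed = 11))

recovery_corpus <- function() cached("corpus", world_corpus(recovery_world()))

recovery_embeddings <- function() {
  cached("emb", {
    w <- recovery_world()
    pretrain_embeddings(w$ontology, w$cooccurrence, dimension = 100, namespace = "BP")
  })
}

# a small world for fast unit tests
tiny_world <- function() {
  cached("tiny", generate_world(
    n_terms = 40, n_topics = 3, n_genes = 30, ann_range = c(2, 4),
    n_documents = 300, seed = 7
  ))
}

tiny_corpus <- function() cached("tiny_corpus", world_corpus(tiny_world()))

# hand-written OBO fixture: root <- parent <- child, plus a diamond
toy_obo_lines <- function() {
  c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", 'def: "The root process." []', "",
    "[Term]", "id: GO:0000002", "name: parent",
    "namespace: biological_process", 'def: "A parent process." []',
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: child",
    "namespace: biological_process", 'def: "A child process." []',
    "is_a: GO:0000002 ! parent", "",
    "[Term]", "id: GO:0000004", "name: second parent",
    "namespace: biological_process", 'def: "Another parent process." []',
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000005", "name: diamond child",
    "namespace: biological_process", 'def: "A diamond child process." []',
    "is_a: GO:0000002 ! parent", "is_a: GO:0000004 ! second parent",
    "alt_id: GO:0000099", "",
    "[Term]", "id: GO:0000010", "name: component",
    "namespace: cellular_component", 'def: "A compartment." []', "",
    "[Term]", "id: GO:0000011", "name: activity",
    "namespace: molecular_function", 'def: "An activity." []', ""
  )
}

gaf_row <- function(gene, term, evidence = "EXP", aspect = "P", qualifier = "") {
  paste(c(
    "DB", gene, gene, qualifier, term, "REF:1", evidence, "", aspect,
    "", "", "protein", "taxon:1", "20240101", "DB", "", ""
  ), collapse = "\t")
}

# random padded index fixtures for network-level tests
random_pair_fixture <- function(vocab = 12L, t0 = 5L, dim = 7L, seed = 1L) {
  withr::with_seed(seed, {
    cfg <- network_config(
      channels = "BP", task = "regression", embedding_dim = dim,
      dropout_rate = 0, seed = seed
    )
    params <- init_fs_params(cfg, c(BP = vocab))
    pad <- function() {
      k <- sample(1:t0, 1)
      c(sort(sample(vocab, k)), rep(0L, t0 - k))
    }
    list(
      cfg = cfg, params = params,
      a = list(BP = pad()), b = list(BP = pad())
    )
  })
}
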