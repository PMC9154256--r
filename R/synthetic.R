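#' Generate a fully synthetic world: ontology, definitions, co-occurrence,
#' annotations
#'
#' Builds a self-contained stand-in for the external resources the pipeline
#' normally consumes (GO structure, term definitions, a literature bigram
#' table, GAF annotations) with known latent structure, so every stage and
#' the parameter-recovery experiments can run without downloads. Terms are
#' organized into latent topics: each topic has a unit center vector, term
#' latent vectors are jittered copies of their topic center, definitions are
#' bags of topic-specific words, the word co-occurrence table is accumulated
#' from simulated topic-coherent documents, and each gene samples its
#' per-namespace annotation sets mostly from its own primary topic. All
#' emitted structures are deterministic functions of `seed`.
#'
#' @param n_terms Terms per sub-ontology, including its root (default 300).
#' @param n_topics Number of latent topics (default 6).
#' @param n_genes Number of genes (default 500).
#' @param ann_range Integer interval: annotations drawn per gene and
#'   namespace (default `c(3, 10)`).
#' @param latent_dim Dimension of the latent term vectors (default 16).
#' @param words_per_topic Topic-specific vocabulary size (default 40).
#' @param n_shared_words Topic-neutral filler words (default 30).
#' @param def_length Interval of definition lengths in words (default
#'   `c(8, 15)`).
#' @param topic_purity Probability that a definition word / an annotation
#'   comes from the term's or gene's own topic (default 0.8).
#' @param n_documents,doc_length Simulated documents feeding the
#'   co-occurrence counts (default 2000 docs of 10 words).
#' @param jitter Norm of the latent perturbation around the unit topic
#'   center (default 0.5, i.e. within-topic cosine around 0.9).
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @return An object of class `synthetic_world` with fields `ontology`
#'   (a `go_ontology` covering BP/CC/MF), `annotations` (tibble gene /
#'   namespace / term_id), `cooccurrence` (`word_cooccurrence`), `latent`
#'   (per-namespace matrix of unit term vectors), `topic_of_term`,
#'   `topic_of_gene`, `params`, `seed`.
#' @export
generate_world <- function(n_terms = 300L, n_topics = 6L, n_genes = 500L,
                           ann_range = c(3L, 10L), latent_dim = 16L,
                           words_per_topic = 40L, n_shared_words = 30L,
                           def_length = c(8L, 15L), topic_purity = 0.8,
                           n_documents = 2000L, doc_length = 10L,
                           jitter = 0.5, seed = 1L) {
  if (n_topics > n_terms - 1L) abort("`n_topics` must be < `n_terms` (root excluded).")
  if (ann_range[1] < 1L || ann_range[2] > n_terms - 1L) {
    abort("`ann_range` must lie within [1, n_terms - 1].")
  }

  withr::with_seed(seed, {
    # --- vocabulary: unique random letter strings, never stopwords ----------
    n_words <- n_topics * words_per_topic + n_shared_words
    make_words <- function(n) {
      w <- character(0)
      while (length(w) < n) {
        cand <- vapply(seq_len(n - length(w)), function(i) {
          paste(sample(letters, 7L, replace = TRUE), collapse = "")
        }, "")
        w <- unique(c(w, setdiff(cand, go_stopwords())))
      }
      w[seq_len(n)]
    }
    words <- make_words(n_words)
    topic_words <- split(words[seq_len(n_topics * words_per_topic)],
      rep(seq_len(n_topics), each = words_per_topic))
    shared_words <- words[n_topics * words_per_topic + seq_len(n_shared_words)]

    unit <- function(v) v / sqrt(sum(v^2))
    centers <- t(apply(matrix(rnorm(n_topics * latent_dim), n_topics), 1, unit))

    sample_def <- function(topic) {
      len <- sample(def_length[1]:def_length[2], 1L)
      own <- stats::rbinom(len, 1L, topic_purity) == 1L & topic > 0L
      toks <- character(len)
      toks[own] <- sample(topic_words[[max(topic, 1L)]], sum(own), replace = TRUE)
      toks[!own] <- sample(shared_words, sum(!own), replace = TRUE)
      toks
    }

    # --- per-namespace DAG, latent vectors, definitions ---------------------
    acc_counter <- 0L
    records <- list()
    latent <- list()
    topic_of_term <- integer(0)
    ns_terms <- list()
    for (ns in GO_NAMESPACES) {
      acc <- sprintf("GO:%07d", acc_counter + seq_len(n_terms))
      acc_counter <- acc_counter + n_terms
      topic <- c(0L, sample(rep_len(seq_len(n_topics), n_terms - 1L)))
      vec <- matrix(0, n_terms, latent_dim, dimnames = list(acc, NULL))
      vec[1L, ] <- unit(rnorm(latent_dim))
      for (i in 2:n_terms) {
        # jitter is the perturbation norm relative to the unit topic center,
        # so cluster tightness does not depend on latent_dim
        vec[i, ] <- unit(centers[topic[i], ] + jitter * unit(rnorm(latent_dim)))
      }
      parents <- vector("list", n_terms)
      parents[[1L]] <- character(0)
      for (i in 2:n_terms) {
        same <- which(topic[seq_len(i - 1L)] == topic[i])
        same <- same[same > 1L]
        parents[[i]] <- if (length(same)) {
          n_par <- min(length(same), sample(1:2, 1L))
          acc[same[sample.int(length(same), n_par)]]
        } else {
          acc[1L]
        }
      }
      ns_full <- names(OBO_NAMESPACE_MAP)[OBO_NAMESPACE_MAP == ns]
      for (i in seq_len(n_terms)) {
        records[[acc[i]]] <- list(
          term_id = acc[i],
          name = sprintf("%s synthetic term %d", ns, i),
          namespace = ns,
          definition = paste0(paste(sample_def(topic[i]), collapse = " "), "."),
          obsolete = FALSE,
          parents = parents[[i]]
        )
      }
      latent[[ns]] <- vec
      topic_of_term <- c(topic_of_term, stats::setNames(topic, acc))
      ns_terms[[ns]] <- acc
    }
    ontology <- new_go_ontology(records, character())

    # --- co-occurrence counts from simulated topic-coherent documents -------
    doc_topics <- sample(n_topics, n_documents, replace = TRUE)
    ii <- integer(0); jj <- integer(0)
    word_id <- stats::setNames(seq_along(words), words)
    for (d in seq_len(n_documents)) {
      own <- stats::rbinom(doc_length, 1L, 0.85) == 1L
      toks <- character(doc_length)
      toks[own] <- sample(topic_words[[doc_topics[d]]], sum(own), replace = TRUE)
      toks[!own] <- sample(shared_words, sum(!own), replace = TRUE)
      idx <- word_id[toks]
      cmb <- utils::combn(idx, 2L)
      ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
    }
    keep <- ii != jj
    counts <- Matrix::sparseMatrix(
      i = c(ii[keep], jj[keep]), j = c(jj[keep], ii[keep]), x = 1,
      dims = c(n_words, n_words), dimnames = list(words, words)
    )
    cooc <- word_cooccurrence(counts)

    # --- genes: topic-biased annotation sets per namespace ------------------
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    topic_of_gene <- stats::setNames(sample(n_topics, n_genes, replace = TRUE), gene_ids)
    ann <- vector("list", n_genes * 3L)
    k <- 0L
    for (g in seq_len(n_genes)) {
      for (ns in GO_NAMESPACES) {
        acc <- ns_terms[[ns]]
        tt <- topic_of_term[acc]
        own_pool <- acc[tt == topic_of_gene[g]]
        other_pool <- acc[tt > 0L & tt != topic_of_gene[g]]
        n_ann <- sample(ann_range[1]:ann_range[2], 1L)
        n_own <- stats::rbinom(1L, n_ann, topic_purity)
        n_own <- min(max(n_own, 1L), length(own_pool), n_ann)
        n_other <- min(n_ann - n_own, length(other_pool))
        n_own <- min(n_ann - n_other, length(own_pool)) # refill if a pool ran short
        terms <- c(
          sample(own_pool, n_own),
          if (n_other > 0L) sample(other_pool, n_other) else character(0)
        )
        k <- k + 1L
        ann[[k]] <- tibble(gene = gene_ids[g], namespace = ns, term_id = terms)
      }
    }
    annotations <- dplyr::bind_rows(ann)

    structure(
      list(
        ontology = ontology, annotations = annotations, cooccurrence = cooc,
        latent = latent, topic_of_term = topic_of_term, topic_of_gene = topic_of_gene,
        params = list(
          n_terms = n_terms, n_topics = n_topics, n_genes = n_genes,
          ann_range = ann_range, latent_dim = latent_dim, jitter = jitter,
          topic_purity = topic_purity
        ),
        seed = seed
      ),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d terms/namespace, %d topics, %d genes (seed %d)\n",
    x$params$n_terms, x$params$n_topics, x$params$n_genes, x$seed
  ))
  invisible(x)
}

#' Annotation corpus of a synthetic world
#'
#' @param world A `synthetic_world`.
#' @return An `annotation_corpus` over the world's genes.
#' @export
world_corpus <- function(world) {
  build_annotation_corpus(world$annotations, include_iea = FALSE)
}

#' Latent ground-truth functional similarity of gene pairs
#'
#' The noiseless score the synthetic tasks are derived from: for genes A and
#' B it is the symmetrized best-match average of latent term cosines —
#' the mean over A's annotation vectors of their maximal cosine to B's
#' vectors, averaged with the same quantity in the other direction. It is
#' symmetric by construction and maximal for a gene paired with itself.
#'
#' @param world A `synthetic_world`.
#' @param gene_a,gene_b Character vectors of equal length.
#' @param namespace Which sub-ontology's annotations to score on (default
#'   `"BP"`).
#' @return Numeric vector of ground-truth FS scores.
#' @export
ground_truth_fs <- function(world, gene_a, gene_b, namespace = "BP") {
  namespace <- match.arg(namespace, GO_NAMESPACES)
  V <- world$latent[[namespace]]
  ann <- world$annotations[world$annotations$namespace == namespace, ]
  sets <- split(ann$term_id, ann$gene)
  vapply(seq_along(gene_a), function(i) {
    A <- V[sets[[gene_a[i]]], , drop = FALSE]
    B <- V[sets[[gene_b[i]]], , drop = FALSE]
    C <- A %*% t(B) # rows are unit vectors, so this is the cosine
    (mean(apply(C, 1, max)) + mean(apply(C, 2, max))) / 2
  }, 0)
}

#' Derive a labeled gene-pair task dataset from the synthetic world
#'
#' Samples distinct unordered gene pairs, computes their latent ground-truth
#' FS and converts it into task targets: `"ppi"` — label 1 for the upper
#' half of the ground-truth scores (exactly balanced), then labels flipped
#' independently with probability `noise_sigma`; `"homology"` — an affine
#' transform of the ground truth plus Gaussian noise of sd `noise_sigma`
#' (log-bitscore-like scale); `"coexpression"` — Fisher-z of the clipped
#' ground truth plus Gaussian noise.
#'
#' @param world A `synthetic_world`.
#' @param task `"ppi"`, `"homology"` or `"coexpression"`.
#' @param n_pairs Number of pairs to sample.
#' @param noise_sigma Noise knob: flip probability (ppi) or Gaussian sd
#'   (continuous tasks).
#' @param seed Integer seed.
#' @param namespace Sub-ontology the ground truth is computed on (default
#'   `"BP"`).
#' @return A `gene_pair_dataset` with the noiseless score kept in column
#'   `truth`.
#' @export
make_task_data <- function(world, task = c("ppi", "homology", "coexpression"),
                           n_pairs = 1000L, noise_sigma = 0.1, seed = 1L,
                           namespace = "BP") {
  task <- match.arg(task)
  genes <- names(world$topic_of_gene)
  max_pairs <- choose(length(genes), 2)
  if (n_pairs > max_pairs) {
    abort(sprintf("n_pairs = %d exceeds the %d available pairs.", n_pairs, max_pairs))
  }
  withr::with_seed(seed, {
    seen <- character(0)
    ga <- character(0); gb <- character(0)
    while (length(ga) < n_pairs) {
      m <- 2L * (n_pairs - length(ga)) + 10L
      a <- sample(genes, m, replace = TRUE)
      b <- sample(genes, m, replace = TRUE)
      ok <- a != b
      lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
      key <- pair_key(lo, hi)
      new <- !key %in% seen & !duplicated(key)
      ga <- c(ga, lo[new]); gb <- c(gb, hi[new]); seen <- c(seen, key[new])
    }
    ga <- ga[seq_len(n_pairs)]; gb <- gb[seq_len(n_pairs)]
    truth <- ground_truth_fs(world, ga, gb, namespace)
    if (sd(truth) == 0) abort("Degenerate world: ground-truth FS has zero variance.")
    target <- switch(task,
      ppi = {
        lab <- as.integer(rank(truth, ties.method = "random") > n_pairs / 2)
        flip <- stats::rbinom(n_pairs, 1L, noise_sigma) == 1L
        ifelse(flip, 1L - lab, lab)
      },
      homology = 4 + 2 * truth + rnorm(n_pairs, 0, noise_sigma),
      coexpression = atanh(pmin(pmax(truth, 0), 1 - 1e-7)) + rnorm(n_pairs, 0, noise_sigma)
    )
    new_gene_pair_dataset(
      tibble(gene_a = ga, gene_b = gb, target = target, truth = truth),
      task = task, seed = seed,
      metadata = list(noise_sigma = noise_sigma, namespace = namespace)
    )
  })
}

#' Write the synthetic world in the external file dialects
#'
#' Emits `world.obo` (OBO 1.2), `world.gaf` (GAF 2.2) and `bigrams.tsv`
#' (3-column word/word/count, upper triangle), exactly the formats
#' [parse_obo()], [parse_gaf()] and [read_cooccurrence()] consume.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obo_file <- file.path(dir, "world.obo")
  gaf_file <- file.path(dir, "world.gaf")
  big_file <- file.path(dir, "bigrams.tsv")

  ns_full <- stats::setNames(names(OBO_NAMESPACE_MAP), OBO_NAMESPACE_MAP)
  ont <- world$ontology
  stanzas <- vapply(seq_len(nrow(ont)), function(i) {
    paste(c(
      "[Term]",
      paste0("id: ", ont$term_id[i]),
      paste0("name: ", ont$name[i]),
      paste0("namespace: ", ns_full[[ont$namespace[i]]]),
      sprintf('def: "%s" []', ont$definition[i]),
      if (length(ont$parents[[i]])) paste0("is_a: ", ont$parents[[i]], " ! parent"),
      ""
    ), collapse = "\n")
  }, "")
  writeLines(c("format-version: 1.2", "ontology: synthetic", "", stanzas), obo_file)

  ann <- world$annotations
  aspect <- stats::setNames(names(GAF_ASPECT_MAP), GAF_ASPECT_MAP)
  rows <- sprintf(
    "SYN\t%s\t%s\t\t%s\tSYN:0000001\tEXP\t\t%s\t\t\tprotein\ttaxon:0001\t20260101\tSYN\t\t",
    ann$gene, ann$gene, ann$term_id, aspect[ann$namespace]
  )
  writeLines(c("!gaf-version: 2.2", rows), gaf_file)

  cc <- methods::as(world$cooccurrence$counts, "TsparseMatrix")
  up <- cc@i <= cc@j
  readr::write_tsv(
    tibble(
      word1 = world$cooccurrence$vocabulary[cc@i[up] + 1L],
      word2 = world$cooccurrence$vocabulary[cc@j[up] + 1L],
      count = cc@x[up]
    ),
    big_file,
    col_names = FALSE
  )
  invisible(c(obo = obo_file, gaf = gaf_file, bigrams = big_file))
}
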