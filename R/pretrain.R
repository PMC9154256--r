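#' Term-feature matrices for definition-based embedding pretraining
#'
#' A `term_feature_matrix` is a sparse terms-by-word-features matrix tagged
#' with its pipeline stage: `first_order` (raw definition word counts),
#' `second_order` (words replaced by their corpus co-occurrence profiles) or
#' `pmi` (positive pointwise mutual information weights).
#'
#' @param m A matrix or sparse Matrix with term accessions as row names and
#'   word features as column names.
#' @param stage One of `"first_order"`, `"second_order"`, `"pmi"`.
#' @return An object of class `term_feature_matrix` with fields `m` and
#'   `stage`.
#' @export
term_feature_matrix <- function(m, stage = c("first_order", "second_order", "pmi")) {
  stage <- match.arg(stage)
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (stage != "pmi" && length(m@x) && any(m@x < 0)) {
    abort(sprintf("%s matrices must be non-negative.", stage))
  }
  structure(list(m = m, stage = stage), class = "term_feature_matrix")
}

#' @export
print.term_feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<term_feature_matrix> stage=%s, %d terms x %d features, %.2f%% nonzero\n",
    x$stage, nrow(x$m), ncol(x$m), 100 * length(x$m@x) / prod(dim(x$m))
  ))
  invisible(x)
}

#' @export
dim.term_feature_matrix <- function(x) dim(x$m)

#' First-order definition vectors: raw word counts
#'
#' Entry (t, w) is the number of times word w occurs in the tokenized
#' definition of term t.
#'
#' @param corpus A `definition_corpus` from [tokenize_definitions()].
#' @param vocabulary Optional fixed word order for the columns; defaults to
#'   the sorted union of all tokens.
#' @return A `term_feature_matrix` at stage `first_order`.
#' @export
first_order_matrix <- function(corpus, vocabulary = NULL) {
  if (!length(corpus)) abort("Definition corpus is empty.")
  vocabulary <- vocabulary %||% sort(unique(unlist(corpus, use.names = FALSE)))
  ii <- rep(seq_along(corpus), lengths(corpus))
  jj <- match(unlist(corpus, use.names = FALSE), vocabulary)
  keep <- !is.na(jj)
  m <- Matrix::sparseMatrix(
    i = ii[keep], j = jj[keep], x = 1,
    dims = c(length(corpus), length(vocabulary)),
    dimnames = list(names(corpus), vocabulary)
  )
  term_feature_matrix(m, "first_order")
}

#' Second-order expansion against a word co-occurrence table
#'
#' Replaces each definition word by its corpus-wide co-occurrence profile and
#' sums the profiles weighted by the word's definition count:
#' `row(t) = sum_w first(t, w) * cooc_row(w)`. This densifies the sparse
#' first-order vectors; words absent from the co-occurrence vocabulary are
#' skipped, and terms whose definitions share no word with that vocabulary
#' are dropped with a warning.
#'
#' @param first A `term_feature_matrix` at stage `first_order`.
#' @param cooc A `word_cooccurrence`.
#' @return A `term_feature_matrix` at stage `second_order`, with the
#'   co-occurrence vocabulary as its columns.
#' @export
second_order_expand <- function(first, cooc) {
  stopifnot(inherits(first, "term_feature_matrix"), inherits(cooc, "word_cooccurrence"))
  if (first$stage != "first_order") abort("`first` must be a first_order matrix.")
  common <- intersect(colnames(first$m), cooc$vocabulary)
  if (!length(common)) abort("No definition word appears in the co-occurrence vocabulary.")
  counts <- first$m[, common, drop = FALSE]
  covered <- Matrix::rowSums(counts) > 0
  if (any(!covered)) {
    warn(sprintf(
      "%d term(s) share no word with the co-occurrence vocabulary and were dropped.",
      sum(!covered)
    ))
    counts <- counts[covered, , drop = FALSE]
  }
  if (!nrow(counts)) abort("All terms dropped in second-order expansion.")
  second <- counts %*% cooc$counts[common, , drop = FALSE]
  term_feature_matrix(second, "second_order")
}

#' Positive pointwise mutual information weighting
#'
#' Treats the matrix as a joint count table: `p(t, w) = x_tw / N` with margins
#' estimated from the row and column sums. Entry (t, w) becomes
#' `max(0, log(p(t, w) / (p(t) p(w))))` (natural log); non-positive
#' associations are clipped to zero, the standard positive-PMI remedy for
#' log-of-zero and negative-association noise. Invariant to uniform scaling
#' of the input counts.
#'
#' @param m A `term_feature_matrix` at stage `second_order` (or
#'   `first_order`).
#' @return A `term_feature_matrix` at stage `pmi`.
#' @export
pmi_weight <- function(m) {
  stopifnot(inherits(m, "term_feature_matrix"))
  if (m$stage == "pmi") abort("Matrix is already PMI-weighted.")
  x <- m$m
  total <- sum(x)
  if (total <= 0) abort("All-zero matrix: PMI is undefined.")
  rs <- Matrix::rowSums(x)
  cs <- Matrix::colSums(x)
  trip <- methods::as(x, "TsparseMatrix")
  i <- trip@i + 1L
  j <- trip@j + 1L
  v <- log(trip@x * total / (rs[i] * cs[j]))
  v[v < 0 | !is.finite(v)] <- 0
  out <- Matrix::sparseMatrix(
    i = i, j = j, x = v, dims = dim(x), dimnames = dimnames(x)
  )
  term_feature_matrix(Matrix::drop0(out), "pmi")
}

#' Embedding tables
#'
#' An `embedding_table` maps term accessions to fixed-dimension real vectors —
#' either pretrained by [lsa_reduce()] or randomly initialized by
#' [random_embeddings()]. The padding index 0 used by [encode_gene()] never
#' maps to a table row; it is resolved to the large-negative padding sentinel
#' at network lookup time.
#'
#' @param vectors Numeric matrix, one row per term, row names = accessions.
#' @param provenance `"pretrained_LSA"` or `"random"`.
#' @return An object of class `embedding_table` with fields `vectors`,
#'   `dimension` and `provenance`.
#' @export
embedding_table <- function(vectors, provenance = c("pretrained_LSA", "random")) {
  provenance <- match.arg(provenance)
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) abort("Embedding vectors need term accessions as row names.")
  structure(
    list(vectors = vectors, dimension = ncol(vectors), provenance = provenance),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf(
    "<embedding_table> %d terms x %d dims (%s)\n",
    nrow(x$vectors), x$dimension, x$provenance
  ))
  invisible(x)
}

#' Latent semantic analysis: truncated SVD of the PMI matrix
#'
#' Computes the rank-`dimension` truncated singular value decomposition of the
#' PMI-weighted term-feature matrix and returns the left singular vectors
#' scaled by their singular values as term embeddings. Signs follow a
#' deterministic convention (the largest-magnitude component of each right
#' singular vector is made positive). With `normalize = TRUE` (default) rows
#' are L2-normalized afterwards so cosine similarity equals the dot product.
#'
#' @param m A `term_feature_matrix` at stage `pmi`.
#' @param dimension Output dimensionality (default 100, matching the
#'   network's embedding layer). Must not exceed the numerical rank of the
#'   matrix.
#' @param normalize L2-normalize the term vectors? Default `TRUE`.
#' @return An `embedding_table` with provenance `pretrained_LSA`.
#' @export
lsa_reduce <- function(m, dimension = 100L, normalize = TRUE) {
  stopifnot(inherits(m, "term_feature_matrix"))
  if (m$stage != "pmi") abort("`m` must be a PMI-weighted matrix; run pmi_weight() first.")
  dense <- as.matrix(m$m)
  if (dimension < 1 || dimension > min(dim(dense))) {
    abort(sprintf("`dimension` must be in [1, %d].", min(dim(dense))))
  }
  s <- svd(dense)
  rank <- sum(s$d > max(dim(dense)) * max(s$d) * .Machine$double.eps)
  if (dimension > rank) {
    abort(sprintf("`dimension` = %d exceeds the matrix rank (%d).", dimension, rank))
  }
  k <- seq_len(dimension)
  u <- s$u[, k, drop = FALSE]
  v <- s$v[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    comp <- v[which.max(abs(v[, j])), j]
    if (comp < 0) -1 else 1
  }, 0)
  vec <- sweep(u, 2, s$d[k] * flip, `*`)
  if (normalize) {
    nrm <- sqrt(rowSums(vec^2))
    nrm[nrm == 0] <- 1
    vec <- vec / nrm
  }
  rownames(vec) <- rownames(dense)
  embedding_table(vec, "pretrained_LSA")
}

#' Random embedding initialization
#'
#' Draws each component from a symmetric zero-mean uniform distribution,
#' the fallback when no pretrained table is supplied to the network.
#'
#' @param terms Character vector of term accessions.
#' @param dimension Embedding dimension (default 100).
#' @param seed Integer seed.
#' @param scale Half-width of the uniform range (default 0.05).
#' @return An `embedding_table` with provenance `random`.
#' @export
random_embeddings <- function(terms, dimension = 100L, seed = 1L, scale = 0.05) {
  withr::with_seed(seed, {
    vec <- matrix(runif(length(terms) * dimension, -scale, scale),
      nrow = length(terms), dimnames = list(terms, NULL)
    )
  })
  embedding_table(vec, "random")
}

#' Cosine nearest neighbors of a term in an embedding table
#'
#' @param table An `embedding_table`.
#' @param term Query term accession (present in the table).
#' @param k Number of neighbors (default 5).
#' @return Tibble with columns `term_id` and `cosine`, sorted by descending
#'   cosine similarity (ties broken by table row order); the query itself is
#'   excluded.
#' @export
nearest_terms <- function(table, term, k = 5L) {
  stopifnot(inherits(table, "embedding_table"))
  if (k < 1) abort("`k` must be >= 1.")
  v <- table$vectors
  row <- match(term, rownames(v))
  if (is.na(row)) abort(sprintf("Term '%s' is not in the embedding table.", term))
  q <- v[row, ]
  qn <- sqrt(sum(q^2))
  nrm <- sqrt(rowSums(v^2))
  if (qn == 0) abort("Query vector has zero norm.")
  cos <- as.vector(v %*% q) / (pmax(nrm, .Machine$double.eps) * qn)
  cos[row] <- -Inf
  ord <- order(-cos, seq_along(cos))
  top <- head(ord, min(k, nrow(v) - 1L))
  tibble(term_id = rownames(v)[top], cosine = unname(cos[top]))
}

#' Write / read an embedding table as tab-separated text
#'
#' One row per term: accession followed by `dimension` floats.
#'
#' @param table An `embedding_table`.
#' @param file Path.
#' @return `write_embeddings()` returns `file` invisibly;
#'   `read_embeddings()` returns the table.
#' @export
write_embeddings <- function(table, file) {
  df <- as.data.frame(table$vectors)
  names(df) <- paste0("d", seq_len(ncol(df)))
  df <- cbind(term_id = rownames(table$vectors), df)
  readr::write_tsv(as_tibble(df), file)
  invisible(file)
}

#' @rdname write_embeddings
#' @param provenance Provenance recorded on the table read back.
#' @export
read_embeddings <- function(file, provenance = "pretrained_LSA") {
  d <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$term_id
  embedding_table(m, provenance)
}

#' Pretrain GO-term embeddings from definitions in one call
#'
#' Convenience chain: tokenize -> first-order -> second-order -> PMI -> LSA.
#'
#' @param ontology A `go_ontology`.
#' @param cooc A `word_cooccurrence`.
#' @param dimension Embedding dimension (default 100).
#' @param namespace Optional sub-ontology filter (`"BP"`, `"CC"`, `"MF"`).
#' @param stopwords Stopword vector for tokenization.
#' @return An `embedding_table`.
#' @export
pretrain_embeddings <- function(ontology, cooc, dimension = 100L, namespace = NULL,
                                stopwords = go_stopwords()) {
  if (!is.null(namespace)) {
    namespace <- match.arg(namespace, GO_NAMESPACES)
    ontology <- ontology[ontology$namespace == namespace, ]
  }
  tokenize_definitions(ontology, stopwords = stopwords) |>
    first_order_matrix() |>
    second_order_expand(cooc) |>
    pmi_weight() |>
    lsa_reduce(dimension = dimension)
}
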