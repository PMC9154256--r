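#' A small English stopword list for definition tokenization
#'
#' Function words that carry no topical signal in GO term definitions.
#' Supplied as the default `stopwords` argument of [tokenize_definitions()];
#' pass your own vector to override.
#'
#' @return Character vector of lower-case stopwords.
#' @export
go_stopwords <- function() {
  c(
    "a", "an", "the", "of", "in", "on", "at", "to", "from", "by", "for",
    "with", "without", "within", "into", "onto", "via", "as", "is", "are",
    "was", "were", "be", "been", "being", "that", "which", "this", "these",
    "those", "it", "its", "their", "there", "where", "when", "whose", "or",
    "and", "but", "not", "no", "nor", "any", "all", "some", "such", "other",
    "than", "then", "thus", "also", "may", "might", "can", "could", "will",
    "would", "shall", "should", "has", "have", "had", "having", "does", "do",
    "did", "done", "more", "most", "less", "least", "very", "both", "each",
    "either", "neither", "between", "among", "during", "through", "over",
    "under", "about", "usually", "typically", "often", "commonly", "involved",
    "involving", "results", "resulting", "example", "obsolete"
  )
}

#' Tokenize GO term definitions into content words
#'
#' Lower-cases the definition text, splits on non-alphabetic characters,
#' and drops stopwords and tokens shorter than `min_length`. Terms whose
#' definitions yield no tokens are dropped with a warning; obsolete terms are
#' skipped.
#'
#' @param ontology A `go_ontology` from [parse_obo()], or any data frame with
#'   `term_id`, `definition` and optionally `obsolete` columns.
#' @param stopwords Character vector of words to remove; default
#'   [go_stopwords()].
#' @param min_length Minimum token length retained (default 2).
#' @return A named list (class `definition_corpus`) mapping term accession to
#'   its character vector of tokens.
#' @export
tokenize_definitions <- function(ontology, stopwords = go_stopwords(), min_length = 2L) {
  if (!nrow(ontology)) abort("Ontology is empty; nothing to tokenize.")
  keep <- if ("obsolete" %in% names(ontology)) !ontology$obsolete else TRUE
  ids <- ontology$term_id[keep]
  defs <- ontology$definition[keep]

  toks <- lapply(defs, function(d) {
    t <- strsplit(tolower(d), "[^a-z]+")[[1]]
    t[nchar(t) >= min_length & !t %in% stopwords]
  })
  names(toks) <- ids
  empty <- lengths(toks) == 0L
  if (any(empty)) {
    warn(sprintf(
      "%d term(s) have no content words after tokenization and were dropped (e.g. %s).",
      sum(empty), ids[empty][1]
    ))
  }
  structure(toks[!empty], class = "definition_corpus")
}

#' Word-word co-occurrence counts
#'
#' Wraps a square sparse matrix of co-occurrence (bigram) counts over a fixed
#' vocabulary; rows are the co-occurrence profiles that
#' [second_order_expand()] substitutes for definition words.
#'
#' @param counts A square matrix or sparse Matrix with identical row and
#'   column names (the vocabulary) and non-negative entries.
#' @return An object of class `word_cooccurrence` with fields `counts`
#'   (`dgCMatrix`) and `vocabulary`.
#' @export
word_cooccurrence <- function(counts) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != ncol(counts) || is.null(rownames(counts)) ||
    !identical(rownames(counts), colnames(counts))) {
    abort("`counts` must be square with identical row/column name vocabularies.")
  }
  if (any(counts@x < 0)) abort("Co-occurrence counts must be non-negative.")
  structure(list(counts = counts, vocabulary = rownames(counts)),
    class = "word_cooccurrence"
  )
}

#' Read co-occurrence counts from a 3-column bigram file
#'
#' Expects a tab-separated file with columns `word1`, `word2`, `count`
#' (no header). With `symmetric = TRUE` (default) each bigram contributes to
#' both the (word1, word2) and (word2, word1) cells.
#'
#' @param file Path to the bigram file.
#' @param symmetric Mirror counts across the diagonal? Default `TRUE`.
#' @return A `word_cooccurrence`.
#' @export
read_cooccurrence <- function(file, symmetric = TRUE) {
  d <- readr::read_tsv(file,
    col_names = c("word1", "word2", "count"),
    col_types = "ccd", progress = FALSE
  )
  vocab <- sort(unique(c(d$word1, d$word2)))
  i <- match(d$word1, vocab)
  j <- match(d$word2, vocab)
  x <- d$count
  if (symmetric) {
    off <- i != j # diagonal counted once
    i2 <- c(i, j[off])
    j2 <- c(j, i[off])
    x <- c(x, x[off])
    i <- i2
    j <- j2
  }
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(vocab), length(vocab)), dimnames = list(vocab, vocab)
  )
  word_cooccurrence(m)
}
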