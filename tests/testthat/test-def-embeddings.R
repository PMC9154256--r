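test_that("tokenize_definitions keeps lower-cased content words", {
  ont <- tibble::tibble(
    term_id = c("GO:1", "GO:2"),
    definition = c("Purine-containing compound metabolic process.", "The of and."),
    obsolete = FALSE
  )
  expect_warning(toks <- tokenize_definitions(ont), "dropped")
  expect_equal(
    toks[["GO:1"]],
    c("purine", "containing", "compound", "metabolic", "process")
  )
  expect_false("GO:2" %in% names(toks)) # stopwords-only definition dropped
  expect_error(tokenize_definitions(ont[0, ]), "empty")
})

test_that("first_order_matrix counts definition words", {
  toks <- structure(
    list(t1 = c("a1", "b1", "a1"), t2 = c("c1", "d1")),
    class = "definition_corpus"
  )
  m <- first_order_matrix(toks)
  expect_equal(m$stage, "first_order")
  dense <- as.matrix(m$m)
  expect_equal(dense["t1", "a1"], 2)
  expect_equal(dense["t1", "b1"], 1)
  # disjoint vocabularies give orthogonal rows
  expect_equal(sum(dense["t1", ] * dense["t2", ]), 0)
  # row sums equal definition lengths
  expect_equal(unname(Matrix::rowSums(m$m)), lengths(toks), ignore_attr = TRUE)
})

test_that("second_order_expand substitutes co-occurrence profiles", {
  toks <- structure(
    list(t1 = c("aa"), t2 = c("aa", "bb"), t3 = c("cc", "cc")),
    class = "definition_corpus"
  )
  first <- first_order_matrix(toks)
  vocab <- c("aa", "bb", "cc", "dd")
  set.seed(3)
  counts <- matrix(rpois(16, 5), 4, 4, dimnames = list(vocab, vocab))
  cooc <- word_cooccurrence(counts)
  second <- second_order_expand(first, cooc)
  expect_equal(second$stage, "second_order")
  # single-word definition -> its co-occurrence row
  expect_equal(as.numeric(second$m["t1", ]), as.numeric(counts["aa", ]))
  # brute-force triple loop oracle
  f <- as.matrix(first$m)
  oracle <- matrix(0, 3, 4, dimnames = list(rownames(f), vocab))
  for (t in rownames(f)) {
    for (w2 in vocab) {
      for (w in colnames(f)) oracle[t, w2] <- oracle[t, w2] + f[t, w] * counts[w, w2]
    }
  }
  expect_equal(as.matrix(second$m), oracle, ignore_attr = TRUE)
  # identity co-occurrence is the identity transform
  id <- word_cooccurrence(diag(3) |> `dimnames<-`(list(c("aa", "bb", "cc"), c("aa", "bb", "cc"))))
  second_id <- second_order_expand(first, id)
  expect_equal(
    as.matrix(second_id$m)[, c("aa", "bb", "cc")],
    as.matrix(first$m)[, c("aa", "bb", "cc")]
  )
  # terms sharing no word with the vocabulary are dropped with a warning
  off <- word_cooccurrence(matrix(1, 1, 1, dimnames = list("aa", "aa")))
  expect_warning(res <- second_order_expand(first, off), "dropped")
  expect_false("t3" %in% rownames(res$m))
})

test_that("pmi_weight matches the probability-ratio definition", {
  # independent margins (rank-1 counts) give PMI 0 everywhere
  u <- c(2, 5, 3)
  v <- c(1, 4, 2, 3)
  rank1 <- term_feature_matrix(
    outer(u, v) |> `dimnames<-`(list(paste0("t", 1:3), paste0("w", 1:4))),
    "second_order"
  )
  expect_equal(max(abs(pmi_weight(rank1)$m)), 0)
  # 2x2 diagonal counts: diagonal log(2), off-diagonal clipped to 0
  diag2 <- term_feature_matrix(
    matrix(c(10, 0, 0, 10), 2, dimnames = list(c("t1", "t2"), c("w1", "w2"))),
    "second_order"
  )
  p <- as.matrix(pmi_weight(diag2)$m)
  expect_equal(unname(diag(p)), rep(log(2), 2))
  expect_equal(p[1, 2], 0)
  # scale invariance
  set.seed(9)
  counts <- matrix(rpois(20 * 30, 3), 20, 30,
    dimnames = list(paste0("t", 1:20), paste0("w", 1:30))
  )
  m1 <- pmi_weight(term_feature_matrix(counts, "second_order"))
  m2 <- pmi_weight(term_feature_matrix(counts * 7, "second_order"))
  expect_equal(as.matrix(m1$m), as.matrix(m2$m), tolerance = 1e-12)
  # brute-force oracle
  N <- sum(counts)
  oracle <- counts * 0
  for (i in 1:20) {
    for (j in 1:30) {
      if (counts[i, j] > 0) {
        oracle[i, j] <- max(0, log(counts[i, j] * N / (sum(counts[i, ]) * sum(counts[, j]))))
      }
    }
  }
  expect_equal(as.matrix(m1$m), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  zero <- term_feature_matrix(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("c", "d"))),
    "second_order")
  expect_error(pmi_weight(zero), "All-zero")
})

test_that("lsa_reduce is a truncated SVD with the Eckart-Young property", {
  set.seed(4)
  x <- matrix(rexp(8 * 12), 8, 12, dimnames = list(paste0("t", 1:8), paste0("w", 1:12)))
  m <- term_feature_matrix(x, "pmi")
  # rank-1 matrix reconstructs exactly at dimension 1
  r1 <- term_feature_matrix(
    outer(1:4, 1:6) |> `dimnames<-`(list(paste0("t", 1:4), paste0("w", 1:6))), "pmi"
  )
  emb1 <- lsa_reduce(r1, 1, normalize = FALSE)
  s1 <- svd(outer(1:4, 1:6))
  recon <- emb1$vectors %*% t(s1$v[, 1, drop = FALSE] * sign(s1$v[which.max(abs(s1$v[, 1])), 1]))
  expect_equal(recon, outer(1:4, 1:6), tolerance = 1e-10, ignore_attr = TRUE)
  # vectors match the dense full-SVD oracle up to the fixed sign convention
  k <- 3
  emb <- lsa_reduce(m, k, normalize = FALSE)
  s <- svd(x)
  for (j in 1:k) {
    flip <- sign(s$v[which.max(abs(s$v[, j])), j])
    expect_equal(emb$vectors[, j], s$u[, j] * s$d[j] * flip,
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
  # Eckart-Young: squared Frobenius error of the rank-k truncation
  for (k in c(1, 3, 5)) {
    e <- lsa_reduce(m, k, normalize = FALSE)
    sv <- svd(x)
    recon <- e$vectors %*% t(sweep(sv$v[, 1:k, drop = FALSE], 2,
      vapply(1:k, function(j) sign(sv$v[which.max(abs(sv$v[, j])), j]), 0), `*`))
    err <- sqrt(sum((x - recon)^2))
    expect_equal(err, sqrt(sum(sv$d[-(1:k)]^2)), tolerance = 1e-8)
  }
  expect_error(lsa_reduce(m, 50), "dimension")
  # normalized rows have unit L2 norm
  nr <- lsa_reduce(m, 3, normalize = TRUE)
  expect_equal(unname(sqrt(rowSums(nr$vectors^2))), rep(1, 8), tolerance = 1e-12)
  expect_error(lsa_reduce(r1, 3), "rank")
})

test_that("nearest_terms ranks by cosine with deterministic ties", {
  vec <- rbind(
    q = c(1, 0, 0),
    dup = c(2, 0, 0), # same direction as the query
    orth = c(0, 1, 0),
    neg = c(-1, 0, 0),
    mix = c(1, 1, 0)
  )
  tab <- embedding_table(vec, "random")
  nn <- nearest_terms(tab, "q", k = 4)
  expect_equal(nn$term_id[1], "dup")
  expect_equal(nn$cosine[1], 1)
  expect_equal(nn$cosine[nn$term_id == "orth"], 0)
  expect_false("q" %in% nn$term_id)
  # brute-force all-pairs oracle on a larger fixture
  set.seed(12)
  V <- matrix(rnorm(20 * 6), 20, dimnames = list(sprintf("t%02d", 1:20), NULL))
  tab2 <- embedding_table(V, "random")
  got <- nearest_terms(tab2, "t07", k = 5)
  cos <- as.vector(V %*% V["t07", ]) / (sqrt(rowSums(V^2)) * sqrt(sum(V["t07", ]^2)))
  names(cos) <- rownames(V)
  cos <- cos[names(cos) != "t07"]
  oracle <- names(sort(cos, decreasing = TRUE))[1:5]
  expect_equal(got$term_id, oracle)
  expect_error(nearest_terms(tab2, "absent"), "not in")
})

test_that("embedding tables round-trip through TSV", {
  set.seed(5)
  tab <- embedding_table(
    matrix(rnorm(12), 3, dimnames = list(c("GO:1", "GO:2", "GO:3"), NULL)),
    "pretrained_LSA"
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(tab, f)
  back <- read_embeddings(f)
  expect_equal(unname(back$vectors), unname(tab$vectors), tolerance = 1e-12)
  expect_equal(rownames(back$vectors), rownames(tab$vectors))
})
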