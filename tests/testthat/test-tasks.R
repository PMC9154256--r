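test_that("build_ppi_dataset balances positives with leak-free negatives", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(1)
  pos <- tibble::tibble(
    gene_a = sprintf("g%02d", 1:10),
    gene_b = sprintf("g%02d", 11:20)
  )
  ds <- build_ppi_dataset(pos, genes, seed = 42)
  expect_equal(nrow(ds), 20)
  expect_equal(sum(ds$target == 1), 10)
  expect_equal(sum(ds$target == 0), 10)
  # no negative equals a positive in either orientation
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  neg <- ds[ds$target == 0, ]
  expect_length(intersect(key(neg$gene_a, neg$gene_b), key(pos$gene_a, pos$gene_b)), 0)
  expect_false(any(neg$gene_a == neg$gene_b))
  # seeding contract
  ds_same <- build_ppi_dataset(pos, genes, seed = 42)
  expect_identical(as.data.frame(ds), as.data.frame(ds_same))
  ds_other <- build_ppi_dataset(pos, genes, seed = 43)
  expect_false(identical(
    as.data.frame(ds[ds$target == 0, ]),
    as.data.frame(ds_other[ds_other$target == 0, ])
  ))
  # universe too small to supply negatives
  tiny <- tibble::tibble(gene_a = "a", gene_b = "b")
  expect_error(build_ppi_dataset(tiny, c("a", "b"), seed = 1), "negatives")
})

test_that("lrbs and rrbs match their closed forms and symmetries", {
  expect_equal(lrbs(100, 100), log(100))
  expect_equal(lrbs(2 * exp(1), 2 * exp(1)), 1 + log(2))
  expect_equal(lrbs(30, 70), lrbs(70, 30))
  expect_error(lrbs(0, 10), "positive")
  expect_equal(rrbs(50, 50, 50, 50), 0)
  expect_equal(rrbs(25, 25, 50, 50), log(1 / 2), tolerance = 1e-12)
  expect_equal(rrbs(25, 25, 50, 50), -0.6931, tolerance = 1e-4)
  # RRBS <= 0 whenever cross-scores do not exceed self-scores
  set.seed(2)
  for (i in 1:20) {
    aa <- runif(1, 50, 100)
    bb <- runif(1, 50, 100)
    ab <- runif(1, 0.1, min(aa, bb))
    ba <- runif(1, 0.1, min(aa, bb))
    expect_lte(rrbs(ab, ba, aa, bb), 0)
  }
  expect_error(rrbs(1, 1, 0, 1), "positive")
})

test_that("build_homology_dataset requires reciprocal hits and self scores", {
  bs <- tibble::tibble(
    query = c("a", "b", "a", "c", "a", "b", "c", "d", "d"),
    subject = c("b", "a", "c", "a", "a", "b", "c", "a", "d"),
    bitscore = c(40, 60, 30, 20, 100, 120, 90, 15, 80)
  )
  ds <- build_homology_dataset(bs)
  # hand enumeration: a-b reciprocal, a-c reciprocal, d-a one direction only
  expect_equal(nrow(ds), 2)
  expect_setequal(paste(ds$gene_a, ds$gene_b), c("a b", "a c"))
  ab <- ds[ds$gene_a == "a" & ds$gene_b == "b", ]
  expect_equal(ab$lrbs, log((40 + 60) / 2))
  expect_equal(ab$rrbs, log((40 + 60) / (100 + 120)))
  expect_true(all(is.finite(ds$lrbs)), all(is.finite(ds$rrbs)))
  expect_equal(ds$target, ds$lrbs)
  ds_r <- build_homology_dataset(bs, score = "rrbs")
  expect_equal(ds_r$target, ds_r$rrbs)
  # missing self score is an error naming the gene
  no_self <- bs[bs$query != "c" | bs$subject != "c", ]
  expect_error(build_homology_dataset(no_self), "'c'")
  # e-value mask applied per direction
  mask <- tibble::tibble(query = c("a", "b"), subject = c("b", "a"))
  ds_m <- build_homology_dataset(bs, evalue_mask = mask)
  expect_equal(nrow(ds_m), 1)
  expect_equal(paste(ds_m$gene_a, ds_m$gene_b), "a b")
})

test_that("coexpression_targets computes Fisher z of absolute Pearson r", {
  set.seed(6)
  expr <- matrix(rnorm(10 * 12), 10, 12, dimnames = list(sprintf("g%02d", 1:10), NULL))
  tg <- coexpression_targets(expr)
  expect_equal(nrow(tg), choose(10, 2))
  # brute-force two-pass oracle
  for (i in sample(nrow(tg), 15)) {
    r <- cor(expr[tg$gene_a[i], ], expr[tg$gene_b[i], ])
    expect_equal(tg$r_abs[i], abs(r), tolerance = 1e-12)
    expect_equal(tg$z[i], atanh(min(abs(r), 1 - 1e-7)), tolerance = 1e-12)
  }
  # closed forms: r = 0 -> z = 0; |r| = 0.5 -> atanh(0.5)
  e2 <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1), c = c(1, 0, -1, 0))
  t2 <- coexpression_targets(e2)
  expect_equal(t2$z[t2$gene_a == "a" & t2$gene_b == "b"], 0)
  expect_equal(atanh(0.5), 0.54931, tolerance = 1e-5)
  # identical rows are clipped to a large finite z
  e3 <- rbind(a = 1:5, b = 1:5, c = c(2, 1, 4, 3, 5))
  t3 <- coexpression_targets(e3)
  expect_true(all(is.finite(t3$z)))
  expect_gt(t3$z[t3$gene_a == "a" & t3$gene_b == "b"], 8)
  # constant gene dropped with a warning; too few conditions error
  e4 <- rbind(a = c(1, 1, 1, 1), b = 1:4, c = c(2, 1, 4, 3))
  expect_warning(t4 <- coexpression_targets(e4), "constant")
  expect_false("a" %in% c(t4$gene_a, t4$gene_b))
  expect_error(coexpression_targets(matrix(1:4, 2, 2)), "conditions")
})

test_that("bin_subsample draws equal counts from five half-open bins", {
  set.seed(8)
  n <- 500
  tg <- tibble::tibble(
    gene_a = sprintf("a%03d", 1:n), gene_b = sprintf("b%03d", 1:n),
    r_abs = runif(n), z = atanh(pmin(runif(n), 1 - 1e-7))
  )
  tg$z <- atanh(pmin(tg$r_abs, 1 - 1e-7))
  ds <- bin_subsample(tg, per_bin = 10, seed = 3)
  expect_equal(nrow(ds), 50)
  expect_equal(unname(table(ds$bin)), rep(10L, 5), ignore_attr = TRUE)
  expect_equal(ds$target, ds$z)
  # boundary convention: 0.2 belongs to the second bin, 1.0 to the fifth
  edge <- tibble::tibble(
    gene_a = c("x1", "x2"), gene_b = c("y1", "y2"),
    r_abs = c(0.2, 1.0), z = atanh(c(0.2, 1 - 1e-7))
  )
  bins <- findInterval(edge$r_abs, seq(0, 1, 0.2), rightmost.closed = TRUE)
  expect_equal(bins, c(2L, 5L))
  # same seed reproduces the subsample
  expect_identical(
    as.data.frame(bin_subsample(tg, 10, seed = 3)),
    as.data.frame(ds)
  )
  # undersized bin errors with occupancies
  few <- tg[tg$r_abs < 0.4, ]
  expect_error(bin_subsample(few, per_bin = 10, seed = 1), "occupanc")
})

test_that("gene pair tables round-trip through TSV", {
  w <- tiny_world()
  ds <- make_task_data(w, "ppi", n_pairs = 40, noise_sigma = 0, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_pairs(ds, f)
  back <- read_gene_pairs(f, task = "ppi")
  expect_equal(back$gene_a, ds$gene_a)
  expect_equal(back$target, ds$target)
})
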