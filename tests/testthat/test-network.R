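test_that("embed_annotations looks up term vectors and fills padding", {
  set.seed(1)
  E <- matrix(rnorm(8 * 4), 8, 4)
  m <- embed_annotations(c(3L, 5L, 0L), E, pad_value = -1e9)
  expect_equal(dim(m), c(4, 3))
  expect_equal(m[, 1], E[3, ])
  expect_equal(m[, 2], E[5, ])
  expect_equal(m[, 3], rep(-1e9, 4))
  # boundary: exactly t0 real terms, no pad columns
  full <- embed_annotations(c(1L, 2L, 4L), E)
  expect_equal(full, t(E[c(1, 2, 4), ]))
  expect_error(embed_annotations(c(9L, 0L), E), "outside")
  expect_error(embed_annotations(c(0L, 3L), E), "trailing")
})

test_that("max_pool_flatten takes per-feature maxima and ignores padding", {
  set.seed(2)
  m <- matrix(rnorm(100 * 5), 100, 5)
  expect_equal(max_pool_flatten(m), apply(m, 1, max))
  # single real column is returned unchanged
  single <- embed_annotations(c(2L, 0L, 0L), matrix(rnorm(12), 3, 4))
  expect_equal(max_pool_flatten(single), single[, 1])
  # appending extra pad columns never changes the output
  padded <- cbind(m, matrix(-1e9, 100, 3))
  expect_identical(max_pool_flatten(padded), max_pool_flatten(m))
  expect_error(max_pool_flatten(matrix(-1e9, 4, 2)), "padding")
})

test_that("gene_representation chains embed, pool, concat and dense ReLU", {
  fx <- random_pair_fixture(seed = 42)
  rep_a <- gene_representation(fx$a, fx$params, fx$cfg)
  expect_length(rep_a, fx$cfg$gene_dense_units)
  # manual chain with the exported primitives
  pooled <- max_pool_flatten(embed_annotations(fx$a$BP, fx$params$embedding$BP))
  manual <- pmax(as.vector(fx$params$gene$W %*% pooled + fx$params$gene$b), 0)
  expect_equal(rep_a, manual, tolerance = 1e-12)
  # zero weights and bias give the zero vector
  p0 <- fx$params
  p0$gene$W[] <- 0
  p0$gene$b[] <- 0
  expect_equal(gene_representation(fx$a, p0, fx$cfg), rep(0, fx$cfg$gene_dense_units))
  # multi-channel width is embedding_dim x 3
  cfg3 <- network_config(channels = c("BP", "CC", "MF"), embedding_dim = 100)
  expect_equal(cfg3$gene_dense_units, 300)
  expect_equal(network_config(channels = "BP", embedding_dim = 100)$gene_dense_units, 100)
})

test_that("highway blends transform and carry through the sigmoid gate", {
  set.seed(7)
  d <- 6
  hp <- list(
    Wh = matrix(rnorm(d * d), d), bh = rnorm(d),
    WT = matrix(rnorm(d * d), d), bT = rnorm(d)
  )
  x <- rnorm(d)
  # element-wise oracle
  h <- 1 / (1 + exp(-(hp$Wh %*% x + hp$bh)))
  tg <- 1 / (1 + exp(-(hp$WT %*% x + hp$bT)))
  expect_equal(highway(x, hp), as.vector(h * tg + x * (1 - tg)), tolerance = 1e-12)
  # saturated gate limits: bT very negative -> carry, very positive -> plain layer
  carry <- hp
  carry$bT <- rep(-30, d)
  carry$WT[] <- 0
  expect_equal(highway(x, carry), x, tolerance = 1e-9)
  plain <- hp
  plain$bT <- rep(30, d)
  plain$WT[] <- 0
  expect_equal(highway(x, plain), as.vector(h), tolerance = 1e-9)
  expect_error(highway(rnorm(3), hp), "width")
})

test_that("forward scores are deterministic, bounded for classification", {
  fx <- random_pair_fixture(seed = 5)
  s1 <- fs_forward(fx$a, fx$b, fx$params, fx$cfg)
  s2 <- fs_forward(fx$a, fx$b, fx$params, fx$cfg)
  expect_identical(s1, s2) # no dropout at inference
  cfg_clf <- fx$cfg
  cfg_clf$task <- "classification"
  for (i in 1:10) {
    fx2 <- random_pair_fixture(seed = i + 100)
    p <- fs_forward(fx2$a, fx2$b, fx2$params, cfg_clf)
    expect_gt(p, 0)
    expect_lt(p, 1)
  }
  # manual full chain equals fs_forward
  ra <- gene_representation(fx$a, fx$params, fx$cfg)
  rb <- gene_representation(fx$b, fx$params, fx$cfg)
  xh <- highway(c(ra, rb), fx$params)
  pp <- pmax(as.vector(fx$params$post$W %*% xh + fx$params$post$b), 0)
  manual <- as.vector(fx$params$head$W %*% pp) + fx$params$head$b
  expect_equal(s1, manual, tolerance = 1e-12)
})

test_that("predict_symmetric averages both orders and is order-invariant", {
  for (i in 1:10) {
    fx <- random_pair_fixture(seed = i)
    ab <- predict_symmetric(fx$a, fx$b, fx$params, fx$cfg)
    ba <- predict_symmetric(fx$b, fx$a, fx$params, fx$cfg)
    expect_identical(ab$score, ba$score)
    expect_equal(ab$score,
      mean(c(
        fs_forward(fx$a, fx$b, fx$params, fx$cfg),
        fs_forward(fx$b, fx$a, fx$params, fx$cfg)
      )),
      tolerance = 1e-15
    )
    # a gene paired with itself: both orders coincide
    aa <- predict_symmetric(fx$a, fx$a, fx$params, fx$cfg)
    expect_equal(aa$score, fs_forward(fx$a, fx$a, fx$params, fx$cfg))
  }
})

test_that("pad-slot extension and annotation permutation leave scores unchanged", {
  for (i in 1:25) {
    fx <- random_pair_fixture(seed = 1000 + i)
    base <- fs_forward(fx$a, fx$b, fx$params, fx$cfg)
    # re-pad to a larger t0
    wider <- list(
      BP = c(fx$a$BP, rep(0L, 4))
    )
    wider_b <- list(BP = c(fx$b$BP, rep(0L, 4)))
    expect_identical(fs_forward(wider, wider_b, fx$params, fx$cfg), base)
    # permute the real annotation indices
    perm <- function(x) {
      real <- x[x != 0L]
      c(real[sample.int(length(real))], rep(0L, length(x) - length(real)))
    }
    pa <- list(BP = perm(fx$a$BP))
    pb <- list(BP = perm(fx$b$BP))
    expect_equal(fs_forward(pa, pb, fx$params, fx$cfg), base, tolerance = 1e-12)
  }
})

test_that("training fits a learnable toy and enforces its preconditions", {
  corp <- tiny_corpus()
  w <- tiny_world()
  ds <- make_task_data(w, "homology", n_pairs = 60, noise_sigma = 0, seed = 2)
  cfg <- network_config(
    channels = "BP", task = "regression", embedding_dim = 16,
    max_epochs = 25, patience = 25, batch_size = 32, seed = 3
  )
  m <- train_fs_model(ds, corp, cfg)
  h <- tidy(m)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1]) # loss decreases
  expect_s3_class(m, "fs_model")
  pred <- predict(m, ds)
  expect_equal(pred$score, (pred$score_ab + pred$score_ba) / 2)
  g <- glance(m)
  expect_equal(g$task, "regression")
  # preconditions
  expect_error(train_fs_model(ds[0, ], corp, cfg), "Empty")
  bad <- ds
  bad$target[1] <- NA
  expect_error(train_fs_model(bad, corp, cfg), "finite")
  cfg_clf <- network_config(channels = "BP", task = "classification", embedding_dim = 16)
  expect_error(train_fs_model(ds, corp, cfg_clf), "0/1")
  stranger <- dplyr::mutate(ds[1:3, ], gene_a = c("nope1", "nope2", "nope3"))
  expect_error(suppressWarnings(train_fs_model(stranger, corp, cfg)), "absent")
})

test_that("compiled and reference training engines agree on deterministic math", {
  corp <- tiny_corpus()
  w <- tiny_world()
  ds <- make_task_data(w, "homology", n_pairs = 50, noise_sigma = 0.05, seed = 4)
  # full-batch, no dropout, fixed epochs: identical optimization trajectories
  cfg <- network_config(
    channels = "BP", task = "regression", embedding_dim = 12,
    dropout_rate = 0, batch_size = 1000, seed = 11
  )
  mr <- train_fs_model(ds, corp, cfg, epochs = 4, engine = "r")
  mc <- train_fs_model(ds, corp, cfg, epochs = 4, engine = "cpp")
  expect_equal(mc$history$train_loss, mr$history$train_loss, tolerance = 1e-12)
  expect_equal(predict(mc, ds)$score, predict(mr, ds)$score, tolerance = 1e-10)
  # classification head too
  dsc <- make_task_data(w, "ppi", n_pairs = 50, noise_sigma = 0, seed = 4)
  cfgc <- network_config(
    channels = "BP", task = "classification", embedding_dim = 12,
    dropout_rate = 0, batch_size = 1000, seed = 11
  )
  mrc <- train_fs_model(dsc, corp, cfgc, epochs = 4, engine = "r")
  mcc <- train_fs_model(dsc, corp, cfgc, epochs = 4, engine = "cpp")
  expect_equal(mcc$history$train_loss, mrc$history$train_loss, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- network_config(
    channels = c("BP", "CC"), task = "regression", embedding_dim = 5,
    dropout_rate = 0, seed = 3
  )
  p <- init_fs_params(cfg, c(BP = 7L, CC = 6L))
  IA <- list(
    BP = matrix(as.integer(rbind(c(1, 3, 0), c(2, 0, 0), c(4, 5, 6), c(7, 1, 2))), 4),
    CC = matrix(as.integer(rbind(c(1, 2), c(3, 0), c(4, 0), c(5, 6))), 4)
  )
  IB <- list(
    BP = matrix(as.integer(rbind(c(2, 0, 0), c(5, 6, 0), c(1, 0, 0), c(3, 4, 0))), 4),
    CC = matrix(as.integer(rbind(c(2, 0), c(1, 5), c(6, 0), c(3, 0))), 4)
  )
  y <- rnorm(4)
  fwb <- deepgofs:::forward_batch
  fw <- fwb(IA, IB, p, cfg, cache = TRUE)
  gr <- deepgofs:::backward_batch(IA, IB, y, fw, p, cfg)
  loss_of <- function(pp) mean((fwb(IA, IB, pp, cfg)$score - y)^2)
  eps <- 1e-6
  check_tensor <- function(get, set, g, k = 6) {
    x <- get(p)
    for (i in sample(length(x), min(k, length(x)))) {
      up <- x
      up[i] <- up[i] + eps
      dn <- x
      dn[i] <- dn[i] - eps
      num <- (loss_of(set(p, up)) - loss_of(set(p, dn))) / (2 * eps)
      expect_equal(as.vector(as.matrix(g))[i], num, tolerance = 1e-4)
    }
  }
  check_tensor(function(p) p$gene$W, function(p, v) {
    p$gene$W <- matrix(v, nrow(p$gene$W))
    p
  }, gr$gene$W)
  check_tensor(function(p) p$highway$Wh, function(p, v) {
    p$highway$Wh <- matrix(v, nrow(p$highway$Wh))
    p
  }, gr$highway$Wh)
  check_tensor(function(p) p$highway$WT, function(p, v) {
    p$highway$WT <- matrix(v, nrow(p$highway$WT))
    p
  }, gr$highway$WT)
  check_tensor(function(p) p$post$W, function(p, v) {
    p$post$W <- matrix(v, nrow(p$post$W))
    p
  }, gr$post$W)
  check_tensor(function(p) p$embedding$BP, function(p, v) {
    p$embedding$BP <- matrix(v, nrow(p$embedding$BP))
    p
  }, gr$embedding$BP, k = 10)
  check_tensor(function(p) p$embedding$CC, function(p, v) {
    p$embedding$CC <- matrix(v, nrow(p$embedding$CC))
    p
  }, gr$embedding$CC, k = 10)
})
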