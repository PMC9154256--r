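#' Configuration of a paired functional-similarity network
#'
#' Collects the architectural and training hyperparameters of the paired
#' network. Widths follow the published architecture: per-channel embedding
#' dimension 100; the gene-level dense layer keeps the concatenated pooled
#' width (100 for a single channel, 300 for all three); the pair-level
#' highway layer operates at twice that (200/600) because the two gene
#' representations are concatenated; the post-highway dense layer maps back
#' to 100/300 before the single-unit head.
#'
#' @param channels Sub-ontology channels, a subset of `c("BP","CC","MF")`;
#'   one channel = single-channel network, all three = multi-channel.
#' @param task `"regression"` (linear head, mean-squared-error loss) or
#'   `"classification"` (sigmoid head, binary cross-entropy loss).
#' @param embedding_dim Embedding dimension per channel (default 100).
#' @param t0 Named integer vector of fixed annotation lengths per channel;
#'   usually taken from the corpus at training time (may be `NULL` here).
#' @param dropout_rate Dropout rate on the dense and highway layers at
#'   training time (default 0.3).
#' @param pad_value Padding sentinel filled in for annotation slots beyond a
#'   gene's real annotations; a large negative value that max-pooling always
#'   suppresses (default -1e9).
#' @param learning_rate,weight_decay,batch_size,max_epochs,patience,validation_fraction
#'   Optimizer settings: adaptive-moment (Adam) step size, decoupled L2
#'   weight decay, minibatch size, epoch cap, early-stopping patience on
#'   validation loss, and the fraction of training pairs held out as the
#'   validation split.
#' @param monitor Early-stopping criterion: `"val_loss"` (default) or, for
#'   classification, `"val_accuracy"` — the validation error rate, which
#'   typically keeps improving after the cross-entropy starts degrading from
#'   confidence miscalibration.
#' @param embedding_lr_scale Multiplier on the learning rate of the embedding
#'   lookup tables (default 0.1). Pretrained embeddings carry most of their
#'   information at initialization; updating them more gently than the dense
#'   layers — the usual discriminative-fine-tuning practice for pretrained
#'   layers — keeps them trainable while limiting how fast they overfit
#'   small pair sets.
#' @param freeze_embeddings Keep the lookup tables fixed during training
#'   (ablation switch); default `FALSE` — embeddings are model parameters.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A list of class `network_config`.
#' @export
network_config <- function(channels = "BP",
                           task = c("regression", "classification"),
                           embedding_dim = 100L,
                           t0 = NULL,
                           dropout_rate = 0.3,
                           pad_value = -1e9,
                           learning_rate = 1e-3,
                           weight_decay = 0,
                           embedding_lr_scale = 0.1,
                           batch_size = 256L,
                           max_epochs = 100L,
                           patience = 5L,
                           validation_fraction = 0.1,
                           monitor = c("val_loss", "val_accuracy"),
                           freeze_embeddings = FALSE,
                           seed = 1L) {
  task <- match.arg(task)
  channels <- match.arg(channels, GO_NAMESPACES, several.ok = TRUE)
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must be in [0, 1).")
  if (pad_value >= 0) abort("`pad_value` must be negative.")
  gene_units <- embedding_dim * length(channels)
  structure(
    list(
      channels = channels, task = task, embedding_dim = as.integer(embedding_dim),
      t0 = t0, dropout_rate = dropout_rate, pad_value = pad_value,
      gene_dense_units = gene_units, pair_units = 2L * gene_units,
      post_highway_units = gene_units,
      learning_rate = learning_rate, weight_decay = weight_decay,
      embedding_lr_scale = embedding_lr_scale,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      validation_fraction = validation_fraction, monitor = match.arg(monitor),
      freeze_embeddings = freeze_embeddings, seed = as.integer(seed)
    ),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> %s | channels %s | dims %d/%d/%d | dropout %.2f | seed %d\n",
    x$task, paste(x$channels, collapse = "+"),
    x$gene_dense_units, x$pair_units, x$post_highway_units,
    x$dropout_rate, x$seed
  ))
  invisible(x)
}

glorot <- function(n_out, n_in) {
  b <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -b, b), n_out, n_in)
}

#' Initialize the parameters of a paired network
#'
#' One lookup table per channel (shared by both legs of the pair — the
#' Siamese weight-sharing contract), gene-level dense weights, highway plain
#' and transform-gate weights, post-highway dense weights and the head. The
#' transform-gate bias starts negative so the gate initially favors carrying
#' the input through.
#'
#' @param config A `network_config`.
#' @param vocab Named integer vector: per-channel vocabulary size (number of
#'   real term indices, excluding the padding index 0).
#' @param init Optional per-channel list of embedding matrices (vocab x dim,
#'   row i = vector of term index i) used to initialize the lookup tables;
#'   channels missing from `init` are randomly initialized.
#' @param seed Seed; defaults to `config$seed`.
#' @return A list of class `fs_params` with elements `embedding` (per-channel
#'   matrix), `gene` (`W`, `b`), `highway` (`Wh`, `bh`, `WT`, `bT`), `post`
#'   (`W`, `b`) and `head` (`W`, `b`).
#' @export
init_fs_params <- function(config, vocab, init = NULL, seed = config$seed) {
  stopifnot(inherits(config, "network_config"))
  d <- config$embedding_dim
  withr::with_seed(seed, {
    embedding <- lapply(stats::setNames(config$channels, config$channels), function(ch) {
      v <- vocab[[ch]]
      if (!is.null(init) && !is.null(init[[ch]])) {
        m <- init[[ch]]
        stopifnot(nrow(m) == v, ncol(m) == d)
        unname(as.matrix(m))
      } else {
        matrix(runif(v * d, -0.05, 0.05), v, d)
      }
    })
    dg <- config$gene_dense_units
    d1 <- config$pair_units
    d2 <- config$post_highway_units
    list(
      embedding = embedding,
      gene = list(W = glorot(dg, dg), b = numeric(dg)),
      highway = list(
        Wh = glorot(d1, d1), bh = numeric(d1),
        WT = glorot(d1, d1), bT = rep(-2, d1)
      ),
      post = list(W = glorot(d2, d1), b = numeric(d2)),
      head = list(W = glorot(1L, d2), b = 0)
    ) |> structure(class = "fs_params")
  })
}

#' Look up the embeddings of a padded annotation index sequence
#'
#' Real term indices map to their lookup-table rows; the padding index 0 maps
#' to a constant column of `pad_value`, the large-negative sentinel that
#' max-pooling suppresses.
#'
#' @param indices Integer vector of length `t0` (real indices first, then
#'   zeros), as produced by [encode_gene()].
#' @param lookup Numeric matrix, row i = embedding of term index i; or an
#'   `embedding_table` (rows used in order).
#' @param pad_value Padding sentinel (default -1e9).
#' @return Numeric matrix of shape `embedding_dim x t0`.
#' @export
embed_annotations <- function(indices, lookup, pad_value = -1e9) {
  if (inherits(lookup, "embedding_table")) lookup <- lookup$vectors
  real <- indices != 0L
  if (any(indices[real] > nrow(lookup) | indices[real] < 0)) {
    abort("Annotation index outside the lookup table.")
  }
  if (any(real & c(FALSE, !real[-length(real)]))) {
    abort("Padding index 0 may only occupy trailing positions.")
  }
  out <- matrix(pad_value, ncol(lookup), length(indices))
  if (any(real)) out[, real] <- t(lookup[indices[real], , drop = FALSE])
  out
}

#' Max-pool an embedding matrix over annotation slots and flatten
#'
#' Component j of the result is the maximum of row j over all columns; since
#' padding columns hold a large negative constant they never win as long as
#' one real annotation column exists.
#'
#' @param m Matrix `embedding_dim x t0` from [embed_annotations()].
#' @param pad_value The padding sentinel used to build `m`.
#' @return Numeric vector of length `embedding_dim`.
#' @export
max_pool_flatten <- function(m, pad_value = -1e9) {
  out <- apply(m, 1L, max)
  if (all(out == pad_value)) {
    abort("All columns are padding: a gene without annotations reached the network.")
  }
  out
}

#' Gene-product representation: embed, pool, concatenate, dense ReLU
#'
#' Per channel, the gene's padded annotation indices are embedded and
#' max-pooled; a multi-channel network concatenates the pooled vectors
#' (width 300 for three channels) before the shared dense ReLU layer whose
#' output is the learned gene-product embedding.
#'
#' @param indices_list Named list (per channel) of padded index vectors.
#' @param params An `fs_params`.
#' @param config A `network_config`.
#' @return Numeric vector of length `config$gene_dense_units`.
#' @export
gene_representation <- function(indices_list, params, config) {
  pooled <- unlist(lapply(config$channels, function(ch) {
    max_pool_flatten(
      embed_annotations(indices_list[[ch]], params$embedding[[ch]], config$pad_value),
      config$pad_value
    )
  }), use.names = FALSE)
  pmax(as.vector(params$gene$W %*% pooled + params$gene$b), 0)
}

#' Highway layer: gated blend of a plain sigmoid layer and the carry path
#'
#' `x' = sigmoid(Wh x + bh) * T + x * (1 - T)` with transform gate
#' `T = sigmoid(WT x + bT)`. When the gate saturates at 0 the layer passes
#' its input through unchanged; at 1 it behaves as a plain layer with
#' sigmoid activation. Input and output widths are equal by construction.
#'
#' @param x Numeric vector.
#' @param params Either an `fs_params` (its `highway` element is used) or a
#'   list with `Wh`, `bh`, `WT`, `bT`.
#' @return Numeric vector, same length as `x`.
#' @export
highway <- function(x, params) {
  hp <- if (!is.null(params$highway)) params$highway else params
  if (ncol(hp$Wh) != length(x) || ncol(hp$WT) != length(x)) {
    abort("Highway weight width does not match the input length.")
  }
  h <- plogis(as.vector(hp$Wh %*% x + hp$bh))
  tg <- plogis(as.vector(hp$WT %*% x + hp$bT))
  h * tg + x * (1 - tg)
}

#' Forward pass of the paired network for one gene pair
#'
#' Chains the two shared-weight legs ([gene_representation()] for each gene),
#' concatenates them, applies the highway layer, the post-highway dense ReLU
#' layer and the task head: a single sigmoid unit (classification,
#' probability in (0,1)) or a single linear unit (regression). Dropout is a
#' training-time device only; inference is deterministic.
#'
#' @param a,b Named lists (per channel) of padded annotation index vectors
#'   for the two genes.
#' @param params An `fs_params`.
#' @param config A `network_config`.
#' @return Raw score for the ordered pair (a, b).
#' @export
fs_forward <- function(a, b, params, config) {
  ra <- gene_representation(a, params, config)
  rb <- gene_representation(b, params, config)
  x <- c(ra, rb)
  xh <- highway(x, params)
  p <- pmax(as.vector(params$post$W %*% xh + params$post$b), 0)
  s <- as.vector(params$head$W %*% p) + params$head$b
  if (config$task == "classification") plogis(s) else s
}

#' Symmetric functional-similarity prediction
#'
#' The highway weights acting on the concatenated pair are not symmetric, so
#' the raw forward score depends on gene order. The reported FS score is the
#' mean of the two orderings, making the symmetry contract exact at
#' prediction time.
#'
#' @inheritParams fs_forward
#' @return A list of class `fs_prediction`: `score` (mean), `score_ab`,
#'   `score_ba`.
#' @export
predict_symmetric <- function(a, b, params, config) {
  sab <- fs_forward(a, b, params, config)
  sba <- fs_forward(b, a, params, config)
  structure(
    list(score = (sab + sba) / 2, score_ab = sab, score_ba = sba),
    class = "fs_prediction"
  )
}

# ---- batched forward/backward ------------------------------------------------
# IA, IB: per-channel integer index matrices (n x t0). Returns score vector and,
# when cache = TRUE, every intermediate needed for backprop. Dropout masks are
# sampled from the current RNG stream when train = TRUE.

pool_channel <- function(I, E, pad_value) {
  .pool_max_cpp(I, E, pad_value)
}

forward_batch <- function(IA, IB, params, config, train = FALSE, cache = FALSE) {
  p_drop <- if (train) config$dropout_rate else 0
  mask <- function(nr, nc) {
    if (p_drop > 0) {
      matrix((runif(nr * nc) >= p_drop) / (1 - p_drop), nr, nc)
    } else {
      NULL
    }
  }
  leg <- function(Ilist, m_gene) {
    pools <- lapply(config$channels, function(ch) {
      pool_channel(Ilist[[ch]], params$embedding[[ch]], config$pad_value)
    })
    Z0 <- do.call(cbind, lapply(pools, `[[`, "P"))
    pre <- Z0 %*% t(params$gene$W) + rep(params$gene$b, each = nrow(Z0))
    H <- pre * (pre > 0)
    Hd <- if (!is.null(m_gene)) H * m_gene else H
    list(pools = pools, Z0 = Z0, H = H, Hd = Hd)
  }
  n <- nrow(IA[[1]])
  mA <- mask(n, config$gene_dense_units)
  mB <- mask(n, config$gene_dense_units)
  la <- leg(IA, mA)
  lb <- leg(IB, mB)
  X <- cbind(la$Hd, lb$Hd)
  Hh <- plogis(X %*% t(params$highway$Wh) + rep(params$highway$bh, each = n))
  Tg <- plogis(X %*% t(params$highway$WT) + rep(params$highway$bT, each = n))
  Xh <- Hh * Tg + X * (1 - Tg)
  mH <- mask(n, config$pair_units)
  Xhd <- if (!is.null(mH)) Xh * mH else Xh
  preP <- Xhd %*% t(params$post$W) + rep(params$post$b, each = n)
  P <- preP * (preP > 0)
  mP <- mask(n, config$post_highway_units)
  Pd <- if (!is.null(mP)) P * mP else P
  s <- as.vector(Pd %*% t(params$head$W)) + params$head$b
  score <- if (config$task == "classification") plogis(s) else s
  if (!cache) {
    return(list(score = score))
  }
  list(
    score = score, s = s, la = la, lb = lb, X = X, Hh = Hh, Tg = Tg, Xh = Xh,
    Xhd = Xhd, P = P, Pd = Pd, mA = mA, mB = mB, mH = mH, mP = mP
  )
}

# gradient of the mean loss wrt all parameters; fw = forward_batch(cache=TRUE)
backward_batch <- function(IA, IB, y, fw, params, config) {
  n <- length(y)
  g_s <- if (config$task == "classification") {
    (fw$score - y) / n # BCE through sigmoid
  } else {
    2 * (fw$score - y) / n # MSE
  }
  gHead_W <- matrix(g_s, 1) %*% fw$Pd
  gHead_b <- sum(g_s)
  dPd <- tcrossprod(g_s, drop(params$head$W)) # n x d2
  dP <- if (!is.null(fw$mP)) dPd * fw$mP else dPd
  dZp <- dP * (fw$P > 0)
  gPost_W <- crossprod(dZp, fw$Xhd)
  gPost_b <- colSums(dZp)
  dXhd <- dZp %*% params$post$W
  dXh <- if (!is.null(fw$mH)) dXhd * fw$mH else dXhd

  dHh <- dXh * fw$Tg
  dTg <- dXh * (fw$Hh - fw$X)
  dZh <- dHh * fw$Hh * (1 - fw$Hh)
  dZT <- dTg * fw$Tg * (1 - fw$Tg)
  gHw_Wh <- crossprod(dZh, fw$X)
  gHw_bh <- colSums(dZh)
  gHw_WT <- crossprod(dZT, fw$X)
  gHw_bT <- colSums(dZT)
  dX <- dXh * (1 - fw$Tg) + dZh %*% params$highway$Wh + dZT %*% params$highway$WT

  dg <- config$gene_dense_units
  gGene_W <- matrix(0, dg, dg)
  gGene_b <- numeric(dg)
  gEmb <- lapply(params$embedding, function(E) NULL)

  for (side in c("a", "b")) {
    leg <- if (side == "a") fw$la else fw$lb
    I <- if (side == "a") IA else IB
    m <- if (side == "a") fw$mA else fw$mB
    dHd <- dX[, if (side == "a") seq_len(dg) else dg + seq_len(dg), drop = FALSE]
    dH <- if (!is.null(m)) dHd * m else dHd
    dZg <- dH * (leg$H > 0)
    gGene_W <- gGene_W + crossprod(dZg, leg$Z0)
    gGene_b <- gGene_b + colSums(dZg)
    dZ0 <- dZg %*% params$gene$W
    off <- 0L
    for (ci in seq_along(config$channels)) {
      ch <- config$channels[ci]
      d <- config$embedding_dim
      G <- dZ0[, off + seq_len(d), drop = FALSE]
      off <- off + d
      # scatter the pooled gradient back onto the winning term vectors
      inc <- .emb_scatter_cpp(
        I[[ch]], leg$pools[[ci]]$A, G, nrow(params$embedding[[ch]])
      )
      gEmb[[ch]] <- if (is.null(gEmb[[ch]])) inc else gEmb[[ch]] + inc
    }
  }

  list(
    embedding = gEmb,
    gene = list(W = gGene_W, b = gGene_b),
    highway = list(Wh = gHw_Wh, bh = gHw_bh, WT = gHw_WT, bT = gHw_bT),
    post = list(W = gPost_W, b = gPost_b),
    head = list(W = gHead_W, b = gHead_b)
  )
}

batch_loss <- function(score, y, task) {
  if (task == "classification") {
    p <- pmin(pmax(score, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((score - y)^2)
  }
}
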