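# ---- Adam optimizer over the nested parameter list ---------------------------

adam_state <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(unclass(params)), v = zero_like(unclass(params)), t = 0L)
}

adam_update <- function(params, grads, state, lr, freeze_embeddings = FALSE,
                        weight_decay = 0, embedding_lr_scale = 1,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  step <- function(p, g, m, v, decay = weight_decay, rate = lr) {
    if (is.null(dim(p))) g <- as.vector(g)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    # decoupled weight decay (AdamW)
    p <- p - rate * ((m / corr1) / (sqrt(v / corr2) + eps) + decay * p)
    list(p = p, m = m, v = v)
  }
  for (blk in names(params)) {
    if (blk == "embedding") {
      if (freeze_embeddings) next
      for (ch in names(params$embedding)) {
        g <- grads$embedding[[ch]]
        if (is.null(g)) next
        u <- step(params$embedding[[ch]], g, state$m$embedding[[ch]], state$v$embedding[[ch]],
          rate = lr * embedding_lr_scale)
        params$embedding[[ch]] <- u$p
        state$m$embedding[[ch]] <- u$m
        state$v$embedding[[ch]] <- u$v
      }
    } else {
      for (nm in names(params[[blk]])) {
        u <- step(params[[blk]][[nm]], grads[[blk]][[nm]], state$m[[blk]][[nm]], state$v[[blk]][[nm]])
        params[[blk]][[nm]] <- u$p
        state$m[[blk]][[nm]] <- u$m
        state$v[[blk]][[nm]] <- u$v
      }
    }
  }
  list(params = params, state = state)
}

# encode the genes of a pair table once per channel; rows follow `pairs`
encode_pair_matrices <- function(pairs, corpus, config) {
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  enc <- lapply(stats::setNames(config$channels, config$channels), function(ch) {
    encode_genes_matrix(corpus, genes, ch)
  })
  list(
    A = lapply(enc, function(E) E[match(pairs$gene_a, genes), , drop = FALSE]),
    B = lapply(enc, function(E) E[match(pairs$gene_b, genes), , drop = FALSE])
  )
}

#' Train a paired functional-similarity network
#'
#' Trains the paired network on a gene-pair dataset. Every training pair is
#' duplicated in reversed gene order (the pair-level weights are not
#' symmetric, so both orders are shown to the optimizer); a fraction of the
#' pairs is held out as a validation split that drives early stopping, and
#' the weights from the best validation epoch are kept. Loss is binary
#' cross-entropy for classification and mean squared error for regression.
#' The embedding lookup tables are parameters of the model and are updated
#' with everything else unless `config$freeze_embeddings` is set.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`, `target` (binary 0/1
#'   for classification, finite real for regression).
#' @param corpus An `annotation_corpus` covering every gene in `pairs`.
#' @param config A `network_config`.
#' @param init Optional `embedding_table` (or per-channel named list of
#'   them) used to initialize the lookup tables; terms present in the corpus
#'   but missing from the table get small random vectors. `NULL` = random
#'   initialization throughout.
#' @param epochs Optional fixed epoch count; disables the validation split
#'   and early stopping (used when refitting on the full training set).
#' @param engine `"cpp"` (default) runs the compiled minibatch loop;
#'   `"r"` runs the pure-R reference implementation of the same math
#'   (kept for auditability and cross-checked in the test suite).
#' @param verbose Print per-epoch losses (`engine = "r"` only)?
#' @return An object of class `fs_model`: fields `params`, `config`,
#'   `corpus`, `history` (tibble of per-epoch train/validation loss),
#'   `best_epoch`, `best_val_loss`, `init_provenance`.
#' @export
train_fs_model <- function(pairs, corpus, config, init = NULL, epochs = NULL,
                           engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "network_config"))
  pairs <- as_tibble(pairs)
  if (!nrow(pairs)) abort("Empty training dataset.")
  if (!all(is.finite(pairs$target))) abort("Targets must be finite.")
  if (config$task == "classification" && !all(pairs$target %in% c(0, 1))) {
    abort("Classification targets must be 0/1.")
  }
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), corpus$genes)
  if (length(missing)) {
    abort(sprintf("%d gene(s) in the dataset are absent from the corpus (e.g. %s).",
      length(missing), missing[1]))
  }
  config$t0 <- corpus$t0[config$channels]

  vocab <- vapply(corpus$terms[config$channels], length, 0L)
  init_tables <- resolve_init_tables(init, corpus, config)
  params <- init_fs_params(config, vocab, init = init_tables$tables)

  set.seed(derive_seed(config$seed, 1L))

  n <- nrow(pairs)
  if (is.null(epochs)) {
    n_val <- max(1L, round(config$validation_fraction * n))
    if (n - n_val < 1L) abort("Too few pairs to split off a validation set.")
    val_idx <- sample(n, n_val)
  } else {
    val_idx <- integer()
  }
  tr <- pairs[setdiff(seq_len(n), val_idx), ]
  va <- pairs[val_idx, ]

  # regression targets are z-scored internally so the head starts near the
  # target scale; predictions are mapped back in predict.fs_model()
  if (config$task == "regression") {
    target_center <- mean(tr$target)
    target_scale <- sd(tr$target)
    if (!is.finite(target_scale) || target_scale == 0) target_scale <- 1
    tr$target <- (tr$target - target_center) / target_scale
    if (nrow(va)) va$target <- (va$target - target_center) / target_scale
  } else {
    target_center <- 0
    target_scale <- 1
  }

  # order augmentation: optimizer sees 2x the training pairs
  tr_aug <- dplyr::bind_rows(
    tr,
    dplyr::rename(tr, gene_a = "gene_b", gene_b = "gene_a")
  )
  enc_tr <- encode_pair_matrices(tr_aug, corpus, config)
  y_tr <- tr_aug$target
  if (nrow(va)) {
    va_aug <- dplyr::bind_rows(va, dplyr::rename(va, gene_a = "gene_b", gene_b = "gene_a"))
    enc_va <- encode_pair_matrices(va_aug, corpus, config)
    y_va <- va_aug$target
  }

  n_tr <- length(y_tr)
  max_epochs <- if (is.null(epochs)) config$max_epochs else as.integer(epochs)
  has_val <- is.null(epochs)

  if (engine == "cpp") {
    res <- .train_core_cpp(
      enc_tr$A, enc_tr$B, y_tr,
      if (has_val) enc_va$A else enc_tr$A,
      if (has_val) enc_va$B else enc_tr$B,
      if (has_val) y_va else y_tr,
      has_val,
      unclass(params), config$channels,
      if (config$task == "classification") 1L else 0L,
      config$pad_value, config$dropout_rate, config$learning_rate,
      config$weight_decay %||% 0, config$embedding_lr_scale %||% 1,
      config$freeze_embeddings, config$batch_size, max_epochs, config$patience,
      if ((config$monitor %||% "val_loss") == "val_accuracy") 1L else 0L
    )
    best_params <- normalize_param_shapes(res$params)
    history <- tibble(
      epoch = seq_along(res$train_loss),
      train_loss = as.numeric(res$train_loss),
      val_loss = if (has_val) as.numeric(res$val_loss) else NA_real_
    )
    return(structure(
      list(
        params = best_params, config = config, corpus = corpus,
        history = history,
        best_epoch = res$best_epoch,
        best_val_loss = if (has_val) res$best_val else NA_real_,
        n_pairs = n,
        target_center = target_center, target_scale = target_scale,
        init_provenance = init_tables$provenance
      ),
      class = "fs_model"
    ))
  }

  opt <- adam_state(params)
  history <- vector("list", max_epochs)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L

  take <- function(enc, idx) {
    list(
      A = lapply(enc$A, function(M) M[idx, , drop = FALSE]),
      B = lapply(enc$B, function(M) M[idx, , drop = FALSE])
    )
  }

  for (epoch in seq_len(max_epochs)) {
    ord <- sample(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    tl <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1L, n_tr)]
      b <- take(enc_tr, idx)
      fw <- forward_batch(b$A, b$B, params, config, train = TRUE, cache = TRUE)
      gr <- backward_batch(b$A, b$B, y_tr[idx], fw, params, config)
      upd <- adam_update(params, gr, opt, config$learning_rate, config$freeze_embeddings,
        weight_decay = config$weight_decay %||% 0,
        embedding_lr_scale = config$embedding_lr_scale %||% 1)
      params <- upd$params
      opt <- upd$state
      tl <- tl + batch_loss(fw$score, y_tr[idx], config$task) * length(idx)
    }
    train_loss <- tl / n_tr
    if (is.null(epochs)) {
      val_score <- forward_batch(enc_va$A, enc_va$B, params, config)$score
      val_loss <- batch_loss(val_score, y_va, config$task)
      crit <- if ((config$monitor %||% "val_loss") == "val_accuracy" &&
        config$task == "classification") {
        mean((val_score >= 0.5) != (y_va >= 0.5))
      } else {
        val_loss
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss, val_loss = val_loss)
      if (verbose) message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, train_loss, val_loss))
      if (crit < best_val - 1e-6) {
        best_val <- crit
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      history[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss, val_loss = NA_real_)
      if (verbose) message(sprintf("epoch %3d  train %.5f", epoch, train_loss))
      best_params <- params
      best_epoch <- epoch
    }
  }

  structure(
    list(
      params = best_params, config = config, corpus = corpus,
      history = dplyr::bind_rows(history),
      best_epoch = best_epoch,
      best_val_loss = if (is.finite(best_val)) best_val else NA_real_,
      n_pairs = n,
      target_center = target_center, target_scale = target_scale,
      init_provenance = init_tables$provenance
    ),
    class = "fs_model"
  )
}

# coerce the parameter list returned by the compiled core back to the shapes
# the R reference path uses (plain numeric biases, 1 x d2 head matrix)
normalize_param_shapes <- function(p) {
  p$gene$b <- as.numeric(p$gene$b)
  p$highway$bh <- as.numeric(p$highway$bh)
  p$highway$bT <- as.numeric(p$highway$bT)
  p$post$b <- as.numeric(p$post$b)
  p$head$W <- matrix(as.numeric(p$head$W), 1L)
  p$head$b <- as.numeric(p$head$b)
  structure(p, class = "fs_params")
}

# align an embedding_table (or per-channel list) to the corpus term indices
resolve_init_tables <- function(init, corpus, config) {
  if (is.null(init)) {
    return(list(tables = NULL, provenance = "random"))
  }
  get_for_channel <- function(ch) {
    tab <- if (inherits(init, "embedding_table")) init else init[[ch]]
    if (is.null(tab)) {
      return(NULL)
    }
    stopifnot(inherits(tab, "embedding_table"))
    terms <- corpus$terms[[ch]]
    d <- config$embedding_dim
    if (tab$dimension != d) {
      abort(sprintf("Embedding table dimension %d != configured %d.", tab$dimension, d))
    }
    hit <- match(terms, rownames(tab$vectors))
    M <- matrix(runif(length(terms) * d, -0.05, 0.05), length(terms), d)
    M[!is.na(hit), ] <- tab$vectors[hit[!is.na(hit)], , drop = FALSE]
    if (anyNA(hit)) {
      warn(sprintf(
        "%d %s term(s) missing from the pretrained table; randomly initialized.",
        sum(is.na(hit)), ch
      ))
    }
    M
  }
  tables <- withr::with_seed(
    derive_seed(config$seed, 99L),
    lapply(stats::setNames(config$channels, config$channels), get_for_channel)
  )
  list(tables = tables, provenance = "pretrained_LSA")
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf(
    "<fs_model> %s, channels %s, %d pairs, init %s, best epoch %d (val loss %.5f)\n",
    x$config$task, paste(x$config$channels, collapse = "+"), x$n_pairs,
    x$init_provenance, x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

#' Predict symmetric functional-similarity scores for gene pairs
#'
#' @param object An `fs_model`.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param corpus Corpus used to encode the genes; defaults to the training
#'   corpus stored in the model.
#' @param ... Unused.
#' @return The `pairs` tibble with columns `score` (order-invariant mean),
#'   `score_ab` and `score_ba` appended.
#' @export
predict.fs_model <- function(object, pairs, corpus = object$corpus, ...) {
  pairs <- as_tibble(pairs)
  enc <- encode_pair_matrices(pairs, corpus, object$config)
  sab <- forward_batch(enc$A, enc$B, object$params, object$config)$score
  sba <- forward_batch(enc$B, enc$A, object$params, object$config)$score
  sab <- sab * object$target_scale + object$target_center
  sba <- sba * object$target_scale + object$target_center
  dplyr::mutate(pairs, score = (sab + sba) / 2, score_ab = sab, score_ba = sba)
}

#' @rdname train_fs_model
#' @param x An `fs_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fs_model <- function(x, ...) x$history

#' @rdname train_fs_model
#' @exportS3Method generics::glance
glance.fs_model <- function(x, ...) {
  tibble(
    task = x$config$task,
    channels = paste(x$config$channels, collapse = "+"),
    n_pairs = x$n_pairs,
    init = x$init_provenance,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' Plot the training history of a fitted pair network
#'
#' @param object An `fs_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.fs_model <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
    names_to = "split", values_to = "loss"
  )
  d <- d[is.finite(d$loss), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "epoch", y = if (object$config$task == "classification") "cross-entropy" else "MSE",
      colour = NULL, title = "Training history"
    ) +
    ggplot2::theme_minimal()
}
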