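#' Gene-grouped fold plan without pair leakage
#'
#' Shuffles the genes (seeded), splits them into `k` near-equal
#' non-overlapping chunks, and derives per-fold pair index lists: the test
#' pairs of fold f are the pairs with at least one gene in chunk f; the
#' training pairs are the pairs with no gene in chunk f. Pairs straddling
#' chunk f and another chunk are therefore test-only in fold f, which
#' guarantees that no training pair shares a gene with the held-out gene set
#' and that every pair is tested at least once per permutation. With
#' `test_rule = "both"` a pair is tested only when both its genes are held
#' out (stricter, but leaves cross-chunk pairs untested).
#'
#' @param genes Character vector of all genes.
#' @param pairs Tibble with columns `gene_a`, `gene_b` (all genes in
#'   `genes`).
#' @param k Number of folds (>= 2, <= number of genes).
#' @param seed Integer permutation seed.
#' @param test_rule `"any"` (default) or `"both"`; see above.
#' @return An object of class `fold_plan` with fields `k`, `seed`,
#'   `fold_of_gene` (named integer) and `folds` — a list of
#'   `list(train = indices, test = indices)` into `pairs`.
#' @export
make_fold_plan <- function(genes, pairs, k = 10L, seed = 1L, test_rule = c("any", "both")) {
  test_rule <- match.arg(test_rule)
  genes <- unique(genes)
  if (k < 2) abort("`k` must be >= 2.")
  if (k > length(genes)) abort(sprintf("k = %d exceeds the %d genes.", k, length(genes)))
  bad <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes)
  if (length(bad)) abort(sprintf("Pair gene '%s' is not in `genes`.", bad[1]))

  fold_of_gene <- withr::with_seed(seed, {
    stats::setNames(rep_len(seq_len(k), length(genes)), sample(genes))
  })
  fa <- fold_of_gene[pairs$gene_a]
  fb <- fold_of_gene[pairs$gene_b]
  folds <- lapply(seq_len(k), function(f) {
    in_f <- fa == f | fb == f
    list(
      train = which(!in_f),
      test = if (test_rule == "any") which(in_f) else which(fa == f & fb == f)
    )
  })
  structure(
    list(k = as.integer(k), seed = seed, fold_of_gene = fold_of_gene, folds = folds,
      test_rule = test_rule),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf(
    "<fold_plan> k=%d, %d genes; train/test pairs per fold: %s\n",
    x$k, length(x$fold_of_gene),
    paste(vapply(x$folds, function(f) sprintf("%d/%d", length(f$train), length(f$test)), ""),
      collapse = " "
    )
  ))
  invisible(x)
}

#' @rdname make_fold_plan
#' @param x A `fold_plan`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fold_plan <- function(x, ...) {
  tibble(
    fold = seq_len(x$k),
    n_test_genes = tabulate(x$fold_of_gene, x$k),
    n_train = vapply(x$folds, function(f) length(f$train), 0L),
    n_test = vapply(x$folds, function(f) length(f$test), 0L)
  )
}

#' F1 score for binary interaction labels
#'
#' `2 TP / (2 TP + FP + FN)` with 1 = interaction as the positive class.
#'
#' @param labels True 0/1 labels (at least one positive).
#' @param predictions Predicted 0/1 labels.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(labels, predictions) {
  if (length(labels) != length(predictions)) abort("Length mismatch.")
  if (!any(labels == 1)) abort("F1 needs at least one true positive label.")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  2 * tp / (2 * tp + fp + fn)
}

#' Pearson and Spearman correlation of predictions with targets
#'
#' Rank ties are handled by average ranks (the standard Spearman
#' convention).
#'
#' @param targets,predictions Numeric vectors of equal length >= 3, neither
#'   constant.
#' @return Named list with elements `pearson` and `spearman`.
#' @export
correlations <- function(targets, predictions) {
  if (length(targets) != length(predictions)) abort("Length mismatch.")
  if (length(targets) < 3) abort("At least 3 points are required.")
  if (sd(targets) == 0 || sd(predictions) == 0) {
    abort("Correlation is undefined for a constant vector.")
  }
  list(
    pearson = cor(targets, predictions, method = "pearson"),
    spearman = cor(targets, predictions, method = "spearman")
  )
}

#' Run a repeated gene-grouped cross-validation experiment
#'
#' For each of `permutations` gene permutations a fresh [make_fold_plan()] is
#' drawn; in each fold a network is trained on the fold's training pairs
#' (with an internal validation split for early stopping) and evaluated on
#' the held-out test pairs. Classification folds report F1 (decision
#' threshold 0.5) and accuracy; regression folds report Pearson and Spearman
#' correlation. The aggregate is the arithmetic mean over all
#' `permutations x k` runs. All fold/permutation seeds derive
#' deterministically from `seed`.
#'
#' @param dataset A `gene_pair_dataset`.
#' @param corpus An `annotation_corpus` covering the dataset's genes.
#' @param config A `network_config` (its `seed` is overridden per run).
#' @param init Optional pretrained `embedding_table` (or per-channel list).
#' @param k Folds per permutation (default 10).
#' @param permutations Number of gene permutations (default 10).
#' @param seed Top-level seed.
#' @param refit After early stopping has selected an epoch count on the
#'   validation split, retrain on the full training pairs for that many
#'   epochs (the published protocol). Default `FALSE`: keep the
#'   best-validation weights.
#' @param test_rule Passed to [make_fold_plan()].
#' @param verbose Print per-fold progress?
#' @return An `evaluation_report`: fields `runs` (tibble of per-run
#'   metrics), `aggregate` (named means), `task`, `k`, `permutations`.
#' @export
run_experiment <- function(dataset, corpus, config, init = NULL, k = 10L,
                           permutations = 10L, seed = 1L, refit = FALSE,
                           test_rule = "any", verbose = FALSE) {
  if (!nrow(dataset)) abort("Empty dataset.")
  task <- config$task
  genes <- sort(unique(c(dataset$gene_a, dataset$gene_b)))
  pairs <- as_tibble(dataset)[, c("gene_a", "gene_b", "target")]

  runs <- list()
  for (p in seq_len(permutations)) {
    plan <- make_fold_plan(genes, pairs, k = k, seed = derive_seed(seed, p), test_rule = test_rule)
    for (f in seq_len(k)) {
      fold <- plan$folds[[f]]
      if (!length(fold$test) || !length(fold$train)) {
        warn(sprintf("Permutation %d fold %d has an empty split; skipped.", p, f))
        next
      }
      cfg <- config
      cfg$seed <- derive_seed(seed, p, f)
      model <- train_fs_model(pairs[fold$train, ], corpus, cfg, init = init)
      if (refit && model$best_epoch > 0L) {
        model <- train_fs_model(pairs[fold$train, ], corpus, cfg, init = init,
          epochs = model$best_epoch)
      }
      test <- pairs[fold$test, ]
      pred <- predict(model, test, corpus = corpus)
      metrics <- if (task == "classification") {
        if (!any(test$target == 1) || !any(test$target == 0)) {
          warn(sprintf("Permutation %d fold %d test split is one-class; skipped.", p, f))
          next
        }
        lab <- as.integer(pred$score >= 0.5)
        list(
          f1 = f1_score(test$target, lab),
          accuracy = mean(lab == test$target)
        )
      } else {
        if (sd(test$target) == 0 || sd(pred$score) == 0) {
          warn(sprintf("Permutation %d fold %d has constant scores; skipped.", p, f))
          next
        }
        correlations(test$target, pred$score)
      }
      n_train_f <- length(fold$train)
      n_test_f <- length(fold$test)
      runs[[length(runs) + 1L]] <- tibble(
        permutation = p, fold = f,
        n_train = n_train_f, n_test = n_test_f,
        best_epoch = model$best_epoch, !!!metrics
      )
      if (verbose) {
        message(sprintf(
          "perm %d fold %d: %s", p, f,
          paste(sprintf("%s=%.4f", names(metrics), unlist(metrics)), collapse = " ")
        ))
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  if (!nrow(runs)) abort("No fold produced a metric.")
  metric_cols <- setdiff(names(runs), c("permutation", "fold", "n_train", "n_test", "best_epoch"))
  structure(
    list(
      runs = runs,
      aggregate = colMeans(runs[metric_cols]),
      task = task, k = k, permutations = permutations, seed = seed
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s, %d runs (%d permutations x %d folds)\n  %s\n",
    x$task, nrow(x$runs), x$permutations, x$k,
    paste(sprintf("%s = %.4f", names(x$aggregate), x$aggregate), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) x$runs

#' @rdname run_experiment
#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(task = x$task, n_runs = nrow(x$runs), k = x$k, permutations = x$permutations),
    as_tibble(as.list(x$aggregate))
  )
}

#' Per-run metric distribution of an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot: one boxplot of per-fold values per metric, with the
#'   aggregate mean marked.
#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  metric_cols <- names(object$aggregate)
  d <- tidyr::pivot_longer(object$runs, dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "value"
  )
  agg <- tibble(metric = metric_cols, value = unname(object$aggregate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::geom_point(data = agg, colour = "red", size = 2) +
    ggplot2::labs(
      x = NULL, y = "per-fold value",
      title = sprintf("%s: mean over %d runs", object$task, nrow(object$runs))
    ) +
    ggplot2::theme_minimal()
}
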