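# canonical unordered pair key, used for leak/duplicate checks everywhere
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

new_gene_pair_dataset <- function(pairs, task, seed = NA_integer_, metadata = list()) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b", "target") %in% names(pairs)))
  if (any(pairs$gene_a == pairs$gene_b)) abort("Self-pairs are not allowed.")
  if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b))) {
    abort("Duplicated gene pair (in some orientation).")
  }
  structure(pairs,
    class = c("gene_pair_dataset", class(pairs)),
    task = task, seed = seed, metadata = metadata
  )
}

#' @export
print.gene_pair_dataset <- function(x, ...) {
  cat(sprintf(
    "<gene_pair_dataset> task=%s, %d pairs, %d genes\n",
    attr(x, "task"), nrow(x), length(unique(c(x$gene_a, x$gene_b)))
  ))
  NextMethod()
}

#' Build a balanced PPI classification dataset
#'
#' Positive interacting pairs are kept as labeled 1; an equal number of
#' negatives is sampled uniformly (without replacement, seeded) from the
#' unordered gene pairs of the universe that are absent from the positive
#' list in either orientation, labeled 0. When a corpus is supplied, genes
#' without GO annotations are removed before sampling.
#'
#' @param positives Tibble/data frame with columns `gene_a`, `gene_b` of
#'   known interactions.
#' @param genes Character vector: the gene universe to draw negatives from.
#' @param seed Integer seed for negative sampling.
#' @param corpus Optional `annotation_corpus`; genes absent from it are
#'   dropped from both positives and the universe.
#' @return A `gene_pair_dataset` (task `"ppi"`) with `target` 1 for
#'   positives, 0 for sampled negatives.
#' @export
build_ppi_dataset <- function(positives, genes, seed = 1L, corpus = NULL) {
  positives <- as_tibble(positives)
  if (!is.null(corpus)) {
    genes <- intersect(genes, corpus$genes)
    keep <- positives$gene_a %in% genes & positives$gene_b %in% genes
    positives <- positives[keep, ]
  }
  positives <- positives[positives$gene_a != positives$gene_b, ]
  positives <- positives[!duplicated(pair_key(positives$gene_a, positives$gene_b)), ]
  n_pos <- nrow(positives)
  if (!n_pos) abort("No positive pairs survive filtering.")
  genes <- sort(unique(genes))
  n_all <- choose(length(genes), 2)
  if (n_all - n_pos < n_pos) {
    abort(sprintf(
      "Universe of %d genes supplies only %d candidate negatives; %d needed.",
      length(genes), n_all - n_pos, n_pos
    ))
  }
  pos_keys <- pair_key(positives$gene_a, positives$gene_b)

  # rejection sampling over canonicalized pairs: simple, exact, seeded
  negatives <- withr::with_seed(seed, {
    seen <- character(0)
    ga <- character(0)
    gb <- character(0)
    while (length(ga) < n_pos) {
      m <- 2L * (n_pos - length(ga)) + 10L
      a <- sample(genes, m, replace = TRUE)
      b <- sample(genes, m, replace = TRUE)
      ok <- a != b
      lo <- pmin(a[ok], b[ok])
      hi <- pmax(a[ok], b[ok])
      key <- pair_key(lo, hi)
      new <- !key %in% pos_keys & !key %in% seen & !duplicated(key)
      ga <- c(ga, lo[new])
      gb <- c(gb, hi[new])
      seen <- c(seen, key[new])
    }
    tibble(gene_a = ga[seq_len(n_pos)], gene_b = gb[seq_len(n_pos)])
  })

  out <- dplyr::bind_rows(
    dplyr::mutate(positives[, c("gene_a", "gene_b")], target = 1),
    dplyr::mutate(negatives, target = 0)
  )
  new_gene_pair_dataset(out, "ppi",
    seed = seed,
    metadata = list(n_positive = n_pos, universe_size = length(genes))
  )
}

#' Log-reciprocal BLAST score
#'
#' `LRBS(A, B) = log((bitscore(A,B) + bitscore(B,A)) / 2)` (natural log).
#' Symmetrizes the directed BLAST bitscores of a protein pair.
#'
#' @param bit_ab,bit_ba Positive directed bitscores for the two query/subject
#'   orientations. Vectorized.
#' @return Numeric vector of LRBS values.
#' @export
lrbs <- function(bit_ab, bit_ba) {
  if (any(bit_ab <= 0 | bit_ba <= 0)) abort("Bitscores must be positive.")
  log((bit_ab + bit_ba) / 2)
}

#' Relative reciprocal BLAST score
#'
#' `RRBS(A, B) = log((bitscore(A,B) + bitscore(B,A)) /
#' (bitscore(A,A) + bitscore(B,B)))` (natural log). Normalizes the reciprocal
#' cross-scores by the two self-alignment scores; identical sequences score 0
#' and it is non-positive whenever cross-scores do not exceed self-scores.
#'
#' @param bit_ab,bit_ba Positive directed cross bitscores.
#' @param bit_aa,bit_bb Positive self-alignment bitscores.
#' @return Numeric vector of RRBS values.
#' @export
rrbs <- function(bit_ab, bit_ba, bit_aa, bit_bb) {
  if (any(c(bit_ab, bit_ba, bit_aa, bit_bb) <= 0)) abort("Bitscores must be positive.")
  log((bit_ab + bit_ba) / (bit_aa + bit_bb))
}

#' Build a sequence-homology dataset from directed BLAST bitscores
#'
#' Retains a protein pair only when a hit is reported in both directions
#' (the reciprocal scores are both needed) and, when an e-value mask is
#' given, only when both directions pass it. Each retained pair carries both
#' the log-reciprocal (LRBS) and relative-reciprocal (RRBS) score; `score`
#' selects which one becomes the training target. With a corpus supplied,
#' pairs with a gene lacking annotations in any of the three sub-ontologies
#' are dropped.
#'
#' @param bitscores Tibble with columns `query`, `subject`, `bitscore`
#'   (directed; self-hits `query == subject` provide the self scores).
#' @param corpus Optional `annotation_corpus` for the all-three-namespaces
#'   filter.
#' @param evalue_mask Optional tibble of directed pairs (`query`, `subject`)
#'   that passed the e-value threshold; defaults to all reported hits.
#' @param score `"lrbs"` (default) or `"rrbs"`: which value to use as
#'   `target`.
#' @return A `gene_pair_dataset` (task `homology_lrbs`/`homology_rrbs`) with
#'   columns `gene_a`, `gene_b`, `lrbs`, `rrbs`, `target`.
#' @export
build_homology_dataset <- function(bitscores, corpus = NULL, evalue_mask = NULL,
                                   score = c("lrbs", "rrbs")) {
  score <- match.arg(score)
  bs <- as_tibble(bitscores)
  stopifnot(all(c("query", "subject", "bitscore") %in% names(bs)))
  if (!is.null(evalue_mask)) {
    mask_keys <- paste(evalue_mask$query, evalue_mask$subject, sep = "\r")
    bs <- bs[bs$query == bs$subject |
      paste(bs$query, bs$subject, sep = "\r") %in% mask_keys, ]
  }
  lookup <- stats::setNames(bs$bitscore, paste(bs$query, bs$subject, sep = "\r"))

  cross <- bs[bs$query != bs$subject, ]
  lo <- pmin(cross$query, cross$subject)
  hi <- pmax(cross$query, cross$subject)
  keys <- paste(lo, hi, sep = "\r")
  both <- keys %in% keys[duplicated(keys)] # reported in both directions
  cand <- unique(tibble(gene_a = lo[both], gene_b = hi[both]))
  if (!nrow(cand)) abort("No pair is reported in both directions.")

  if (!is.null(corpus)) {
    full <- vapply(corpus$annotations, function(g) all(lengths(g) > 0), TRUE)
    ok_genes <- corpus$genes[full]
    cand <- cand[cand$gene_a %in% ok_genes & cand$gene_b %in% ok_genes, ]
    if (!nrow(cand)) abort("No pair survives the annotation filter.")
  }

  need_self <- unique(c(cand$gene_a, cand$gene_b))
  self <- lookup[paste(need_self, need_self, sep = "\r")]
  if (anyNA(self)) {
    abort(sprintf(
      "Missing self bitscore for gene '%s'.", need_self[which(is.na(self))[1]]
    ))
  }

  b_ab <- lookup[paste(cand$gene_a, cand$gene_b, sep = "\r")]
  b_ba <- lookup[paste(cand$gene_b, cand$gene_a, sep = "\r")]
  b_aa <- lookup[paste(cand$gene_a, cand$gene_a, sep = "\r")]
  b_bb <- lookup[paste(cand$gene_b, cand$gene_b, sep = "\r")]
  out <- dplyr::mutate(cand,
    lrbs = unname(lrbs(b_ab, b_ba)),
    rrbs = unname(rrbs(b_ab, b_ba, b_aa, b_bb))
  )
  out$target <- out[[score]]
  new_gene_pair_dataset(out, paste0("homology_", score),
    metadata = list(n_reported = nrow(bs))
  )
}

#' Fisher-z co-expression targets for all gene pairs
#'
#' Computes the absolute Pearson correlation of every gene pair over the
#' expression conditions and applies Fisher's z transform
#' (`atanh`); correlations of exactly 1 in magnitude are clipped to
#' `1 - 1e-7` beforehand to keep the targets finite. Genes with constant
#' expression are dropped with a warning.
#'
#' @param expr Numeric matrix, genes x conditions, with gene row names; at
#'   least 3 conditions.
#' @return Tibble with columns `gene_a`, `gene_b`, `r_abs`, `z` for every
#'   unordered pair.
#' @export
coexpression_targets <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) abort("At least 3 expression conditions are required.")
  if (is.null(rownames(expr))) abort("Expression matrix needs gene row names.")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("%d gene(s) with constant expression dropped.", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) abort("Fewer than 2 variable genes remain.")
  cm <- cor(t(expr))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r_abs <- abs(cm[idx])
  tibble(
    gene_a = rownames(expr)[idx[, 1]],
    gene_b = rownames(expr)[idx[, 2]],
    r_abs = r_abs,
    z = atanh(pmin(r_abs, 1 - 1e-7))
  )
}

#' Bin-balanced subsampling of co-expression pairs
#'
#' Assigns each pair's absolute correlation to one of five bins of width 0.2
#' (half-open, the last bin closed at 1) and samples exactly `per_bin` pairs
#' uniformly (seeded) from each bin, so the returned dataset covers the
#' correlation range evenly. Fisher-z values are carried as targets.
#'
#' @param targets Tibble from [coexpression_targets()] (columns `gene_a`,
#'   `gene_b`, `r_abs`, `z`).
#' @param per_bin Number of pairs sampled per bin.
#' @param seed Integer seed.
#' @return A `gene_pair_dataset` (task `"coexpression"`, `target = z`) with
#'   an additional `bin` column; `5 * per_bin` rows.
#' @export
bin_subsample <- function(targets, per_bin, seed = 1L) {
  breaks <- seq(0, 1, by = 0.2)
  bin <- findInterval(targets$r_abs, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), 5L)
  occ <- tabulate(bin, 5L)
  if (any(occ < per_bin)) {
    abort(sprintf(
      "Bin occupancies %s cannot supply %d pairs per bin.",
      paste(occ, collapse = "/"), per_bin
    ))
  }
  picked <- withr::with_seed(seed, {
    unlist(lapply(1:5, function(b) sample(which(bin == b), per_bin)), use.names = FALSE)
  })
  out <- dplyr::mutate(targets[picked, ], bin = bin[picked], target = .data$z)
  new_gene_pair_dataset(out, "coexpression",
    seed = seed,
    metadata = list(per_bin = per_bin, occupancies = occ)
  )
}

#' Read / write gene-pair tables
#'
#' Tab-separated `gene_a`, `gene_b`, `target` with a header.
#'
#' @param file Path.
#' @param task Task label attached on read.
#' @return A `gene_pair_dataset` / invisibly the file path.
#' @export
read_gene_pairs <- function(file, task = "ppi") {
  d <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  new_gene_pair_dataset(d, task)
}

#' @rdname read_gene_pairs
#' @param dataset A `gene_pair_dataset`.
#' @export
write_gene_pairs <- function(dataset, file) {
  readr::write_tsv(as_tibble(dataset), file)
  invisible(file)
}

#' Distribution of targets in a gene-pair dataset
#'
#' @param object A `gene_pair_dataset`.
#' @param ... Unused.
#' @return A ggplot histogram (or bar chart for binary labels) of `target`.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_pair_dataset <- function(object, ...) {
  task <- attr(object, "task")
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$target))
  p <- if (task == "ppi") {
    p + ggplot2::geom_bar(width = 0.4)
  } else {
    p + ggplot2::geom_histogram(bins = 30)
  }
  p + ggplot2::labs(title = sprintf("%s targets (%d pairs)", task, nrow(d))) +
    ggplot2::theme_minimal()
}
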