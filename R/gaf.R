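#' Parse GO annotations in GAF format into an annotation corpus
#'
#' Reads a GAF 2.1/2.2 file, applies the evidence-code filters used throughout
#' the package (ND rows always dropped; IEA rows dropped unless
#' `include_iea = TRUE`; `NOT`-qualified rows dropped), resolves accessions
#' against the ontology (following `alt_id` aliases, skipping obsolete or
#' unknown terms with a warning) and indexes the surviving terms per
#' sub-ontology. Genes left without annotations in all three sub-ontologies
#' are removed.
#'
#' @param file Path to a GAF file, or a character vector of GAF lines.
#' @param ontology A `go_ontology` from [parse_obo()].
#' @param include_iea Keep rows with evidence code `IEA`? Default `FALSE`.
#' @param id_column Which GAF column identifies the gene product:
#'   `"db_object_id"` (column 2, default) or `"db_object_symbol"` (column 3).
#' @return An `annotation_corpus`; see [build_annotation_corpus()].
#' @export
parse_gaf <- function(file, ontology, include_iea = FALSE,
                      id_column = c("db_object_id", "db_object_symbol")) {
  id_column <- match.arg(id_column)
  txt <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  txt <- txt[!startsWith(txt, "!")]
  txt <- txt[nzchar(txt)]
  if (!length(txt)) abort("GAF input contains no annotation rows.")

  fields <- strsplit(txt, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    abort(sprintf("GAF row %d has %d columns; at least 9 expected.", which(nf < 9L)[1], min(nf)))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  ann <- tibble(
    gene = col(if (id_column == "db_object_id") 2L else 3L),
    qualifier = col(4L),
    term_id = col(5L),
    evidence = col(7L),
    aspect = col(9L)
  )

  ann <- dplyr::filter(
    ann,
    !grepl("(^|\\|)NOT($|\\|)", .data$qualifier),
    .data$evidence != "ND",
    include_iea | .data$evidence != "IEA"
  )

  canonical <- resolve_term_id(ontology, ann$term_id)
  unknown <- is.na(canonical)
  if (any(unknown)) {
    warn(sprintf(
      "%d annotation row(s) reference terms absent from the ontology (e.g. %s); skipped.",
      sum(unknown), ann$term_id[unknown][1]
    ))
  }
  ann$term_id <- canonical
  ann <- ann[!unknown, ]

  obs <- ontology$obsolete[match(ann$term_id, ontology$term_id)]
  if (any(obs)) {
    warn(sprintf("%d annotation row(s) reference obsolete terms; skipped.", sum(obs)))
    ann <- ann[!obs, ]
  }
  ann$namespace <- ontology$namespace[match(ann$term_id, ontology$term_id)]

  build_annotation_corpus(
    dplyr::distinct(ann, .data$gene, .data$namespace, .data$term_id),
    include_iea = include_iea
  )
}

#' Build an annotation corpus from a (gene, namespace, term) table
#'
#' The corpus holds, per sub-ontology, a contiguous term index (accessions
#' mapped to integers starting at 1; index 0 is reserved for padding), each
#' gene's annotation index sets, and the fixed annotation length `t0` — the
#' largest annotation-set size observed over genes, to which [encode_gene()]
#' pads.
#'
#' @param annotations Tibble/data frame with columns `gene`, `namespace`
#'   (`"BP"`/`"CC"`/`"MF"`) and `term_id`.
#' @param include_iea Bookkeeping flag recording how the table was filtered.
#' @return An object of class `annotation_corpus` with fields `genes`,
#'   `annotations` (gene -> list of sorted integer index vectors per
#'   sub-ontology), `term_index` (per sub-ontology named integer vector,
#'   accession -> index), `terms` (per sub-ontology accession vector in index
#'   order) and `t0` (named integer vector).
#' @export
build_annotation_corpus <- function(annotations, include_iea = NA) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("gene", "namespace", "term_id") %in% names(annotations)))
  annotations <- dplyr::distinct(
    annotations[annotations$namespace %in% GO_NAMESPACES, c("gene", "namespace", "term_id")]
  )
  if (!nrow(annotations)) abort("No genes survive annotation filtering; corpus would be empty.")

  terms <- lapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES), function(ns) {
    sort(unique(annotations$term_id[annotations$namespace == ns]))
  })
  term_index <- lapply(terms, function(tt) stats::setNames(seq_along(tt), tt))

  genes <- sort(unique(annotations$gene))
  ann_split <- split(annotations, annotations$gene)
  per_gene <- lapply(ann_split, function(d) {
    lapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES), function(ns) {
      ids <- d$term_id[d$namespace == ns]
      sort(unname(term_index[[ns]][ids]))
    })
  })[genes]

  t0 <- vapply(stats::setNames(GO_NAMESPACES, GO_NAMESPACES), function(ns) {
    max(vapply(per_gene, function(g) length(g[[ns]]), 0L))
  }, 0L)

  structure(
    list(
      genes = genes, annotations = per_gene, term_index = term_index,
      terms = terms, t0 = t0, include_iea = include_iea
    ),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf(
    "<annotation_corpus> %d genes; terms %s; t0 %s\n",
    length(x$genes),
    paste(sprintf("%s: %d", GO_NAMESPACES, vapply(x$terms, length, 0L)), collapse = ", "),
    paste(sprintf("%s: %d", GO_NAMESPACES, x$t0), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname build_annotation_corpus
#' @param x An `annotation_corpus`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.annotation_corpus <- function(x, ...) {
  purrr::map_dfr(x$genes, function(g) {
    purrr::map_dfr(GO_NAMESPACES, function(ns) {
      idx <- x$annotations[[g]][[ns]]
      if (!length(idx)) return(NULL)
      tibble(gene = g, namespace = ns, term_id = x$terms[[ns]][idx])
    })
  })
}

#' Replace annotations by their higher-level ancestor terms
#'
#' Each annotated term is replaced by the union of its `levels`-step `is_a`
#' ancestors (1 = parents, 2 = grandparents, ...). Root terms — terms with no
#' `is_a` parent — map to themselves, so repeated lifting converges on the
#' sub-ontology roots. Term indices and `t0` are recomputed.
#'
#' @param corpus An `annotation_corpus`.
#' @param ontology The `go_ontology` the corpus was built against.
#' @param levels Number of `is_a` steps to climb; integer >= 1.
#' @return A new `annotation_corpus`.
#' @export
lift_annotations <- function(corpus, ontology, levels = 1L) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1) {
    abort("`levels` must be a single integer >= 1.")
  }
  levels <- as.integer(levels)
  pm <- parent_map(ontology)

  lift_one <- function(ids) {
    for (step in seq_len(levels)) {
      ids <- unique(unlist(lapply(ids, function(id) {
        p <- pm[[id]]
        if (is.null(p) || !length(p)) id else p # roots are fixed points
      }), use.names = FALSE))
    }
    sort(ids)
  }

  long <- tidy(corpus)
  lifted <- long |>
    dplyr::group_by(.data$gene, .data$namespace) |>
    dplyr::summarise(term_id = list(lift_one(.data$term_id)), .groups = "drop") |>
    tidyr::unnest("term_id")
  build_annotation_corpus(lifted, include_iea = corpus$include_iea)
}

#' Encode a gene's annotations as a fixed-length padded index sequence
#'
#' Returns the gene's sorted annotation term indices in the requested
#' sub-ontology, padded with the reserved index 0 up to the corpus-wide fixed
#' length `t0`. The padding index is resolved to a large-negative sentinel
#' vector at embedding lookup ([embed_annotations()]), which max-pooling then
#' suppresses.
#'
#' @param corpus An `annotation_corpus`.
#' @param gene Gene identifier present in the corpus.
#' @param namespace `"BP"`, `"CC"` or `"MF"`.
#' @param strict Error when the gene has no annotations in `namespace`
#'   (default); with `strict = FALSE` an all-padding sequence is returned.
#' @return Integer vector of length `corpus$t0[namespace]`.
#' @export
encode_gene <- function(corpus, gene, namespace, strict = TRUE) {
  namespace <- match.arg(namespace, GO_NAMESPACES)
  idx <- corpus$annotations[[gene]]
  if (is.null(idx)) abort(sprintf("Gene '%s' is not in the corpus.", gene))
  idx <- idx[[namespace]]
  if (!length(idx) && strict) {
    abort(sprintf("Gene '%s' has no %s annotations (strict mode).", gene, namespace))
  }
  c(idx, rep(0L, corpus$t0[[namespace]] - length(idx)))
}

# all genes at once: n_genes x t0 integer matrix (rownames = genes)
encode_genes_matrix <- function(corpus, genes, namespace) {
  t0 <- corpus$t0[[namespace]]
  out <- matrix(0L, length(genes), t0, dimnames = list(genes, NULL))
  for (i in seq_along(genes)) {
    idx <- corpus$annotations[[genes[i]]][[namespace]]
    if (!length(idx)) abort(sprintf("Gene '%s' has no %s annotations.", genes[i], namespace))
    out[i, seq_along(idx)] <- idx
  }
  out
}

#' Write / read an annotation corpus as plain text
#'
#' The corpus is stored as a tab-separated annotation table
#' (`annotations.tsv`: gene, sub-ontology, comma-joined GO accessions) plus a
#' term-index sidecar (`term_index.tsv`: namespace, accession, index).
#'
#' @param corpus An `annotation_corpus`.
#' @param dir Directory to write to (created if needed).
#' @return `write_annotation_corpus()` returns `dir` invisibly;
#'   `read_annotation_corpus()` returns the corpus.
#' @export
write_annotation_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- tidy(corpus) |>
    dplyr::group_by(.data$gene, .data$namespace) |>
    dplyr::summarise(terms = paste(.data$term_id, collapse = ","), .groups = "drop")
  readr::write_tsv(long, file.path(dir, "annotations.tsv"))
  idx <- purrr::map_dfr(GO_NAMESPACES, function(ns) {
    tibble(namespace = ns, term_id = corpus$terms[[ns]], index = seq_along(corpus$terms[[ns]]))
  })
  readr::write_tsv(idx, file.path(dir, "term_index.tsv"))
  invisible(dir)
}

#' @rdname write_annotation_corpus
#' @export
read_annotation_corpus <- function(dir) {
  long <- readr::read_tsv(file.path(dir, "annotations.tsv"), show_col_types = FALSE) |>
    dplyr::mutate(term_id = strsplit(.data$terms, ",", fixed = TRUE)) |>
    tidyr::unnest("term_id")
  build_annotation_corpus(long[, c("gene", "namespace", "term_id")])
}
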