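#' Parse a GO ontology in OBO format
#'
#' Reads an OBO 1.2/1.4 file and returns one record per `[Term]` stanza with
#' the fields the rest of the package needs: accession, name, definition text,
#' sub-ontology and direct `is_a` parents. Alternative identifiers (`alt_id`)
#' are aliased to their canonical record so that annotation files using
#' superseded accessions still resolve.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#' @return A tibble of class `go_ontology` with columns `term_id`, `name`,
#'   `namespace` (`"BP"`, `"CC"` or `"MF"`), `definition`, `obsolete` and a
#'   list-column `parents` of direct `is_a` parent accessions. The alt-id
#'   alias map is stored in `attr(, "alt_ids")` (named character vector,
#'   alias -> canonical accession).
#' @examples
#' obo <- c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root process",
#'   "namespace: biological_process", "def: \"The root.\" []"
#' )
#' parse_obo(obo)
#' @export
parse_obo <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- sub("!.*$", "", lines) # trailing OBO comments
  lines <- trimws(lines)

  stanza_starts <- grep("^\\[", lines)
  records <- list()
  alt_map <- character()

  if (length(stanza_starts) == 0L) {
    return(new_go_ontology(records, alt_map))
  }

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    header <- lines[stanza_starts[i]]
    if (header != "[Term]") next # [Typedef] etc. are skipped
    body_idx <- seq(stanza_starts[i] + 1L, bounds[i + 1L] - 1L)
    body_idx <- body_idx[nzchar(lines[body_idx])]
    body <- lines[body_idx]

    bad <- !grepl("^[A-Za-z_]+:", body)
    if (any(bad)) {
      abort(sprintf(
        "Malformed OBO stanza: line %d (%s) has no 'tag: value' form.",
        body_idx[which(bad)[1]], body[which(bad)[1]]
      ))
    }
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[A-Za-z_]+:", "", body))

    id <- vals[tags == "id"][1]
    if (is.na(id)) {
      abort(sprintf("Malformed OBO stanza starting at line %d: missing 'id'.", stanza_starts[i]))
    }
    ns_raw <- vals[tags == "namespace"][1]
    obsolete <- isTRUE(tolower(vals[tags == "is_obsolete"][1]) == "true")
    if (!is.na(ns_raw) && !ns_raw %in% names(OBO_NAMESPACE_MAP)) {
      abort(sprintf(
        "Term %s has namespace '%s'; expected one of %s.",
        id, ns_raw, paste(names(OBO_NAMESPACE_MAP), collapse = ", ")
      ))
    }
    def_raw <- vals[tags == "def"][1]
    definition <- if (is.na(def_raw)) "" else {
      m <- regmatches(def_raw, regexpr('"(\\\\.|[^"])*"', def_raw))
      if (length(m)) gsub('\\\\(.)', "\\1", substr(m, 2L, nchar(m) - 1L)) else def_raw
    }
    parents <- unique(sub("\\s.*$", "", vals[tags == "is_a"]))
    alts <- vals[tags == "alt_id"]
    if (length(alts)) alt_map[alts] <- id

    records[[id]] <- list(
      term_id = id,
      name = vals[tags == "name"][1] %||% "",
      namespace = if (is.na(ns_raw)) NA_character_ else unname(OBO_NAMESPACE_MAP[ns_raw]),
      definition = definition,
      obsolete = obsolete,
      parents = parents
    )
  }
  new_go_ontology(records, alt_map)
}

new_go_ontology <- function(records, alt_map) {
  out <- tibble(
    term_id = unname(vapply(records, `[[`, "", "term_id")),
    name = unname(vapply(records, function(r) r$name %||% "", "")),
    namespace = unname(vapply(records, `[[`, "", "namespace")),
    definition = unname(vapply(records, `[[`, "", "definition")),
    obsolete = unname(vapply(records, `[[`, TRUE, "obsolete")),
    parents = unname(lapply(records, `[[`, "parents"))
  )
  attr(out, "alt_ids") <- alt_map
  class(out) <- c("go_ontology", class(out))
  out
}

#' Resolve term accessions against an ontology, following alt_id aliases
#'
#' @param ontology A `go_ontology` from [parse_obo()].
#' @param term_ids Character vector of GO accessions.
#' @return Character vector of canonical accessions; `NA` where the accession
#'   is unknown.
#' @export
resolve_term_id <- function(ontology, term_ids) {
  alt <- attr(ontology, "alt_ids") %||% character()
  hit <- term_ids %in% ontology$term_id
  out <- ifelse(hit, term_ids, unname(alt[term_ids]))
  out[!out %in% ontology$term_id] <- NA_character_
  out
}

# named list term_id -> character vector of is_a parents (canonical ids only)
parent_map <- function(ontology) {
  stats::setNames(ontology$parents, ontology$term_id)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf(
    "<go_ontology> %d terms (%s)\n", nrow(x),
    paste(sprintf("%s: %d", GO_NAMESPACES, table(factor(x$namespace, GO_NAMESPACES))),
      collapse = ", "
    )
  ))
  NextMethod()
}
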