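#' Build a local ontology term resolver
#'
#' The resolver answers exact-match lookups of attribute values against
#' ontology terms, the way an exact term search against an ontology
#' service does: a value matches a term if it equals the term's
#' preferred label, one of its synonyms, or its identifier,
#' case-insensitively after trimming surrounding whitespace. No fuzzy or
#' partial matching is performed -- `"lung_squamous_carcinoma"` does not
#' match a label that differs only by underscores.
#'
#' The index file is tab-delimited with columns `ontology` (acronym),
#' `term_id`, `preferred_label`, and `synonyms` (pipe-separated, may be
#' empty). The shipped fixture `metaqc_file("term_index.tsv")` carries a
#' synthetic subset of DOID, NCBITaxon, PATO, UBERON, CL, CLO, ENVO and
#' EFO terms sufficient for testing. A resolver backed by a remote
#' exact-search service can be substituted anywhere a resolver is
#' accepted, as long as it honours the same contract.
#'
#' @param path Path to a term-index TSV.
#' @return A `term_resolver` object.
#' @export
term_resolver <- function(path) {
  idx <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("ontology", "term_id", "preferred_label", "synonyms")
  if (!all(need %in% names(idx))) {
    stop("term index must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  table <- new.env(parent = emptyenv())
  add <- function(ontology, key, id) {
    for (scope in c(ontology, "ANY")) {
      k <- paste0(scope, "\r", tolower(key))
      table[[k]] <- unique(c(table[[k]], id))
    }
  }
  for (i in seq_len(nrow(idx))) {
    id <- idx$term_id[[i]]
    onto <- idx$ontology[[i]]
    add(onto, idx$preferred_label[[i]], id)
    add(onto, id, id)
    syns <- strsplit(idx$synonyms[[i]], "|", fixed = TRUE)[[1]]
    for (s in syns[nzchar(trimws(syns))]) add(onto, trimws(s), id)
  }
  structure(list(table = table, n_terms = nrow(idx),
                 ontologies = sort(unique(idx$ontology))),
            class = "term_resolver")
}

#' @export
print.term_resolver <- function(x, ...) {
  cat(sprintf("<term_resolver> %d terms across %d ontologies (%s)\n",
              x$n_terms, length(x$ontologies),
              paste(x$ontologies, collapse = ", ")))
  invisible(x)
}

#' Resolve a value to ontology term identifiers
#'
#' @param resolver A [term_resolver()].
#' @param value A single attribute value; the empty string resolves to
#'   nothing.
#' @param ontology Ontology acronym to search, or `"ANY"` to search
#'   every indexed ontology (used for attributes bound to "any
#'   biomedical ontology").
#' @return Character vector of matching term identifiers (possibly
#'   empty).
#' @export
resolve_term <- function(resolver, value, ontology = "ANY") {
  stopifnot(inherits(resolver, "term_resolver"), length(value) == 1L)
  value <- tolower(trimws(value))
  if (is.na(value) || !nzchar(value)) return(character())
  hits <- resolver$table[[paste0(ontology, "\r", value)]]
  if (is.null(hits)) character() else hits
}
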