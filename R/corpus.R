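#' The sample-corpus container
#'
#' A `sample_corpus` holds one parsed corpus of sample metadata records in
#' two tidy tables: `records`, with one row per sample record, and
#' `attributes`, with one row per attribute (name-value pair) occurrence.
#' Attribute order within a record is preserved via the `position` column,
#' and duplicate attribute names are kept: a record may legitimately repeat
#' a name. Names and values are stored verbatim as submitted; whitespace
#' trimming and any normalisation happen downstream, in the registry lookup
#' and the validators, so that name censuses count syntactically distinct
#' strings.
#'
#' `records` columns (all character): `record_id`, `accession`,
#' `repository` ("NCBI" or "EBI"), `title`, `publication_date`,
#' `last_update_date`, `submission_date`, `organism_name`,
#' `organism_taxon_id`, `owner`, `package`. Dates are raw text as found in
#' the input; year extraction is a report-time concern. A missing package
#' is `NA` at parse time and mapped to "Generic"/"Unpackaged" only when
#' reporting.
#'
#' `attributes` columns: `accession`, `position` (integer), `name`,
#' `value`, `term_source_ref`, `term_source_id` (the last two carried by
#' the SampleTab dialect only).
#'
#' @param records,attributes Tibbles with the columns described above.
#' @param parse_log Optional tibble of parse diagnostics (`level`,
#'   `message`), as produced by the readers.
#' @return An object of class `sample_corpus`.
#' @export
sample_corpus <- function(records = empty_records(),
                          attributes = empty_attributes(),
                          parse_log = NULL) {
  records <- tibble::as_tibble(records)
  attributes <- tibble::as_tibble(attributes)
  rec_cols <- names(empty_records())
  attr_cols <- names(empty_attributes())
  missing_rec <- setdiff(rec_cols, names(records))
  if (length(missing_rec)) {
    stop("records is missing columns: ", paste(missing_rec, collapse = ", "),
         call. = FALSE)
  }
  missing_attr <- setdiff(attr_cols, names(attributes))
  if (length(missing_attr)) {
    stop("attributes is missing columns: ", paste(missing_attr, collapse = ", "),
         call. = FALSE)
  }
  records <- records[rec_cols]
  attributes <- attributes[attr_cols]
  if (nrow(records) && any(is.na(records$accession) | records$accession == "")) {
    stop("every record needs a non-empty accession", call. = FALSE)
  }
  if (nrow(attributes) && any(is.na(attributes$name) |
                              trimws(attributes$name) == "")) {
    stop("attribute names must be non-empty after trimming", call. = FALSE)
  }
  bad_repo <- setdiff(unique(records$repository), c("NCBI", "EBI"))
  if (length(bad_repo)) {
    stop("unknown repository: ", paste(bad_repo, collapse = ", "), call. = FALSE)
  }
  if (is.null(parse_log)) parse_log <- empty_parse_log()
  structure(list(records = records, attributes = attributes,
                 parse_log = tibble::as_tibble(parse_log)),
            class = "sample_corpus")
}

empty_records <- function() {
  tibble::tibble(record_id = character(), accession = character(),
                 repository = character(), title = character(),
                 publication_date = character(), last_update_date = character(),
                 submission_date = character(), organism_name = character(),
                 organism_taxon_id = character(), owner = character(),
                 package = character())
}

empty_attributes <- function() {
  tibble::tibble(accession = character(), position = integer(),
                 name = character(), value = character(),
                 term_source_ref = character(), term_source_id = character())
}

empty_parse_log <- function() {
  tibble::tibble(level = character(), message = character())
}

#' @export
print.sample_corpus <- function(x, ...) {
  repo <- unique(x$records$repository)
  cat(sprintf("<sample_corpus> %d records, %d attributes (%s)\n",
              nrow(x$records), nrow(x$attributes),
              if (length(repo)) paste(repo, collapse = "+") else "empty"))
  dup <- duplicated_accessions(x)
  if (length(dup)) {
    cat(sprintf("  %d duplicated accession(s)\n", length(dup)))
  }
  if (nrow(x$parse_log)) {
    cat(sprintf("  %d parse log entries\n", nrow(x$parse_log)))
  }
  invisible(x)
}

#' Number of records in a corpus
#' @param corpus A [sample_corpus()].
#' @return Integer count.
#' @export
n_records <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  nrow(corpus$records)
}

#' Accessions that occur more than once in a corpus
#'
#' Accessions are expected to be unique within one parsed corpus; readers
#' flag duplicates in the parse log but keep the records, leaving the
#' de-duplication policy to the caller.
#'
#' @param corpus A [sample_corpus()].
#' @return Character vector of duplicated accessions (possibly empty).
#' @export
duplicated_accessions <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  acc <- corpus$records$accession
  sort(unique(acc[duplicated(acc)]))
}

#' Parse diagnostics collected while reading a corpus
#' @param corpus A [sample_corpus()].
#' @return A tibble with columns `level` and `message`.
#' @export
parse_log <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  corpus$parse_log
}
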