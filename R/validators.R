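#' Value-class validators
#'
#' Each validator decides whether attribute values are *well-specified*
#' under one value class, returning `"well_specified"` or `"invalid"`
#' per value. All validators trim surrounding whitespace first and are
#' vectorised; a value that is empty or all whitespace is invalid, not
#' untested.
#'
#' * `validate_boolean()`: the value must be `true` or `false` in any
#'   capitalisation. Abbreviations and synonyms (`f`, `yes`, `Y`, `0`,
#'   `never smoker`, ...) are invalid.
#' * `validate_integer()`: the value must parse as an integer -- an
#'   optional single leading sign followed by decimal digits only. No
#'   floats, thousands separators, or scientific notation.
#' * `validate_timestamp()`: the value must match one of the accepted
#'   date shapes `D-Mmm-YYYY`, `Mmm-YYYY` or `YYYY` (e.g. `20-Nov-2000`,
#'   `Nov-2000`, `2000`; 1-2 digit day 1-31, English three-letter month
#'   matched case-insensitively, 4-digit year) or the ISO 8601 shapes
#'   `YYYY-mm`, `YYYY-mm-dd` or `YYYY-mm-ddThh:mm:ss` with zero-padded
#'   components (month 01-12, day 01-31, hour 00-23, minute/second
#'   00-59). These are format checks only: no calendar arithmetic (day
#'   31 passes for any month), no timezone designators, no semantic
#'   bound on the year.
#' * `validate_value_set()`: the value must equal some member of the
#'   closed value set, ignoring letter case; internal characters must
#'   match exactly, so `mal e` or `femLE` fail against the sex set.
#'
#' @param values Character vector of attribute values.
#' @param value_set Non-empty character vector of permitted values.
#' @return Character vector of statuses, one per value:
#'   `"well_specified"` or `"invalid"`.
#' @name value-validators
NULL

status_of <- function(ok) ifelse(ok, "well_specified", "invalid")

#' @rdname value-validators
#' @export
validate_boolean <- function(values) {
  status_of(tolower(trimws(values)) %in% c("true", "false"))
}

#' @rdname value-validators
#' @export
validate_integer <- function(values) {
  status_of(grepl("^[+-]?[0-9]+$", trimws(values)))
}

.months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
.mmm <- paste0("(?i:", paste(.months, collapse = "|"), ")")
.day <- "(0?[1-9]|[12][0-9]|3[01])"
.timestamp_res <- c(
  paste0("^", .day, "-", .mmm, "-[0-9]{4}$"),
  paste0("^", .mmm, "-[0-9]{4}$"),
  "^[0-9]{4}$",
  "^[0-9]{4}-(0[1-9]|1[0-2])$",
  "^[0-9]{4}-(0[1-9]|1[0-2])-(0[1-9]|[12][0-9]|3[01])$",
  paste0("^[0-9]{4}-(0[1-9]|1[0-2])-(0[1-9]|[12][0-9]|3[01])",
         "T([01][0-9]|2[0-3]):[0-5][0-9]:[0-5][0-9]$"))

#' @rdname value-validators
#' @export
validate_timestamp <- function(values) {
  v <- trimws(values)
  ok <- rep(FALSE, length(v))
  for (re in .timestamp_res) {
    ok <- ok | grepl(re, v, perl = TRUE)
  }
  status_of(ok)
}

#' @rdname value-validators
#' @export
validate_value_set <- function(values, value_set) {
  if (!length(value_set)) {
    stop("value_set must be non-empty", call. = FALSE)
  }
  status_of(tolower(trimws(values)) %in% tolower(value_set))
}

#' Validate values as ontology terms
#'
#' An ontology-term attribute is well-specified when its value
#' exact-matches a term (label, synonym, or identifier) in the
#' designated ontology; see [term_resolver()] for the matching contract.
#' A resolver failure (e.g. an unreachable remote backend) yields
#' `"untested"` rather than silently marking values invalid.
#'
#' @param values Character vector of attribute values.
#' @param ontology Ontology acronym, or `"ANY"`.
#' @param resolver A [term_resolver()].
#' @return Character vector of statuses (`"well_specified"`,
#'   `"invalid"`, or `"untested"` on resolver error).
#' @export
resolve_and_validate_term <- function(values, ontology, resolver) {
  vapply(values, function(v) {
    hits <- tryCatch(resolve_term(resolver, v, ontology),
                     error = function(e) NULL)
    if (is.null(hits)) return("untested")
    if (length(hits)) "well_specified" else "invalid"
  }, character(1), USE.NAMES = FALSE)
}

#' Validate one attribute against a registry
#'
#' Dispatches on the spec found by [lookup_spec()]: no spec, or a spec
#' of class `unchecked`, gives status `untested` (reason `no_spec` /
#' `unchecked`); otherwise the class validator decides and the reason
#' codes the failure (`not_boolean`, `not_integer`, `bad_date_format`,
#' `not_in_value_set`, `no_ontology_match`, `resolver_error`).
#'
#' @param name,value Attribute name and value.
#' @param registry A `spec_registry`.
#' @param resolver A [term_resolver()]; only consulted for
#'   ontology-term specs.
#' @param accession Optional accession carried into the result.
#' @return One-row tibble: `accession`, `attribute_name`, `value`,
#'   `value_class`, `status`, `reason`.
#' @export
validate_attribute <- function(name, value, registry, resolver = NULL,
                               accession = NA_character_) {
  res <- validate_attribute_table(
    tibble::tibble(accession = accession, name = name, value = value),
    registry, resolver)
  res
}

#' Validate every attribute of a corpus
#'
#' Runs the per-class validators over all attribute occurrences of a
#' corpus, one verdict per occurrence, order preserved (duplicate names
#' within a record each get their own verdict).
#'
#' @param corpus A [sample_corpus()].
#' @param registry A `spec_registry` matching the corpus dialect.
#' @param resolver A [term_resolver()] for ontology-term attributes.
#' @return A tibble of validation results: `accession`,
#'   `attribute_name`, `value`, `value_class`, `status`, `reason`.
#' @export
validate_corpus <- function(corpus, registry, resolver = NULL) {
  stopifnot(inherits(corpus, "sample_corpus"))
  validate_attribute_table(corpus$attributes, registry, resolver)
}

#' Validate the attributes of a single record
#'
#' @param corpus A [sample_corpus()].
#' @param accession Accession of the record to validate.
#' @inheritParams validate_corpus
#' @return A validation-result tibble, one row per attribute occurrence
#'   of the record, in attribute order.
#' @export
validate_record <- function(corpus, accession, registry, resolver = NULL) {
  stopifnot(inherits(corpus, "sample_corpus"))
  attrs <- corpus$attributes[corpus$attributes$accession == accession, ]
  validate_attribute_table(attrs, registry, resolver)
}

reason_for_class <- c(boolean = "not_boolean", integer = "not_integer",
                      timestamp = "bad_date_format",
                      value_set = "not_in_value_set",
                      ontology_term = "no_ontology_match")

validate_attribute_table <- function(attrs, registry, resolver) {
  stopifnot(inherits(registry, "spec_registry"))
  n <- nrow(attrs)
  row <- spec_row(registry, attrs$name)
  value_class <- ifelse(is.na(row), NA_character_,
                        registry$specs$value_class[row])
  status <- rep("untested", n)
  reason <- ifelse(is.na(row), "no_spec",
                   ifelse(value_class == "unchecked", "unchecked",
                          NA_character_))

  for (cls in c("boolean", "integer", "timestamp")) {
    sel <- which(!is.na(value_class) & value_class == cls)
    if (!length(sel)) next
    status[sel] <- switch(cls,
      boolean = validate_boolean(attrs$value[sel]),
      integer = validate_integer(attrs$value[sel]),
      timestamp = validate_timestamp(attrs$value[sel]))
  }
  vs_sel <- which(!is.na(value_class) & value_class == "value_set")
  if (length(vs_sel)) {
    set_name <- registry$specs$value_set[row[vs_sel]]
    for (s in unique(set_name)) {
      idx <- vs_sel[set_name == s]
      status[idx] <- validate_value_set(attrs$value[idx],
                                        registry$value_sets[[s]])
    }
  }
  ont_sel <- which(!is.na(value_class) & value_class == "ontology_term")
  if (length(ont_sel)) {
    if (is.null(resolver)) {
      status[ont_sel] <- "untested"
      reason[ont_sel] <- "resolver_error"
    } else {
      onto <- registry$specs$ontology[row[ont_sel]]
      for (o in unique(onto)) {
        idx <- ont_sel[onto == o]
        status[idx] <- resolve_and_validate_term(attrs$value[idx], o, resolver)
        reason[idx][status[idx] == "untested"] <- "resolver_error"
      }
    }
  }
  checked <- !is.na(value_class) & value_class != "unchecked" &
    !(reason %in% "resolver_error")
  reason[checked] <- ifelse(status[checked] == "invalid",
                            reason_for_class[value_class[checked]],
                            NA_character_)
  tibble::tibble(accession = attrs$accession %||% NA_character_,
                 attribute_name = attrs$name,
                 value = attrs$value,
                 value_class = value_class,
                 status = status,
                 reason = reason)
}
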