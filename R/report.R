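#' Summarise validation results by value class
#'
#' Aggregates per-attribute verdicts into the per-class quality table:
#' for every checked value class, the number of records carrying at
#' least one attribute of that class, the number of those records whose
#' class attributes are all well-specified, the attribute totals, and
#' the percentage well-specified (0-100; exact, not rounded -- round for
#' display). Untested attributes (no spec, unchecked class, resolver
#' failures) are excluded from the table.
#'
#' @param results Validation results from [validate_corpus()].
#' @param accessions Optional character vector restricting the summary
#'   to a subset of records, e.g. the packaged subset from
#'   [packaged_accessions()] or a cross-repository accession
#'   intersection. `NULL` (the default) summarises everything.
#' @return A tibble with one row per value class: `value_class`,
#'   `records_with_class`, `records_all_valid`, `attributes_total`,
#'   `attributes_well_specified`, `attributes_invalid`,
#'   `percent_well_specified`.
#' @export
summarize_by_type <- function(results, accessions = NULL) {
  if (!is.null(accessions)) {
    results <- results[results$accession %in% accessions, ]
  }
  checked <- results[results$status %in% c("well_specified", "invalid"), ]
  if (!nrow(checked)) {
    return(tibble::tibble(value_class = character(),
                          records_with_class = integer(),
                          records_all_valid = integer(),
                          attributes_total = integer(),
                          attributes_well_specified = integer(),
                          attributes_invalid = integer(),
                          percent_well_specified = double()))
  }
  checked |>
    dplyr::group_by(.data$value_class) |>
    dplyr::summarise(
      records_with_class = dplyr::n_distinct(.data$accession),
      records_all_valid = dplyr::n_distinct(
        .data$accession[!.data$accession %in%
                          .data$accession[.data$status == "invalid"]]),
      attributes_total = dplyr::n(),
      attributes_well_specified = sum(.data$status == "well_specified"),
      attributes_invalid = sum(.data$status == "invalid"),
      .groups = "drop") |>
    dplyr::mutate(percent_well_specified =
                    100 * .data$attributes_well_specified /
                    .data$attributes_total) |>
    dplyr::arrange(.data$value_class)
}

#' Accessions of records that declare a non-Generic package
#'
#' @param corpus A [sample_corpus()].
#' @return Character vector of accessions.
#' @export
packaged_accessions <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  pkg <- record_packages(corpus)
  corpus$records$accession[!pkg$package %in% c("Generic", "Unpackaged")]
}

# package label per record: NCBI records fall back to "Generic" when the
# package element is absent; EBI records take the value of their
# "package" attribute when present, else "Unpackaged".
record_packages <- function(corpus) {
  recs <- corpus$records
  pkg <- recs$package
  is_ebi <- recs$repository == "EBI"
  if (any(is_ebi)) {
    pkg_attr <- corpus$attributes[corpus$attributes$name == "package", ]
    pkg_attr <- pkg_attr[!duplicated(pkg_attr$accession), ]
    ebi_pkg <- pkg_attr$value[match(recs$accession, pkg_attr$accession)]
    pkg[is_ebi] <- ifelse(is.na(ebi_pkg[is_ebi]), "Unpackaged",
                          ebi_pkg[is_ebi])
  }
  pkg[!is_ebi & is.na(pkg)] <- "Generic"
  tibble::tibble(accession = recs$accession, package = pkg)
}

#' Distribution of records over packages
#'
#' NCBI records without a package element count as `Generic`; EBI
#' records count under the value of their `package` attribute when they
#' carry one, else as `Unpackaged`. Counts sum to the corpus size.
#'
#' @param corpus A [sample_corpus()].
#' @return A tibble `package`, `n`, `percent`, sorted by descending
#'   count.
#' @export
package_distribution <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  record_packages(corpus) |>
    dplyr::count(.data$package, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$package)
}

#' Record submissions per year
#'
#' The year is the leading 4-digit field of the raw submission date;
#' records whose date does not start with four digits (including
#' missing dates) fall into the `"unknown"` bucket.
#'
#' @param corpus A [sample_corpus()].
#' @param split When `TRUE`, counts are split between Generic and
#'   non-Generic records (per [record_packages()]).
#' @return A tibble `year`, `n` (plus `package_group` when split),
#'   years ascending with `"unknown"` last.
#' @export
submissions_per_year <- function(corpus, split = FALSE) {
  stopifnot(inherits(corpus, "sample_corpus"))
  dates <- corpus$records$submission_date
  year <- ifelse(!is.na(dates) & grepl("^[0-9]{4}([^0-9]|$)", dates),
                 substr(dates, 1, 4), "unknown")
  tab <- tibble::tibble(year = year)
  if (split) {
    pkg <- record_packages(corpus)$package
    tab$package_group <- ifelse(pkg == "Generic", "Generic", "non-Generic")
    out <- dplyr::count(tab, .data$year, .data$package_group, name = "n")
  } else {
    out <- dplyr::count(tab, .data$year, name = "n")
  }
  out[order(out$year == "unknown", out$year), ]
}

#' Census of attribute-name usage
#'
#' Counts syntactically unique attribute names (exact strings after
#' surrounding-whitespace trim; case-sensitive) and splits them into
#' dictionary names and submitter-invented custom names via
#' [classify_name()].
#'
#' @param corpus A [sample_corpus()].
#' @param registry A `spec_registry`.
#' @return A one-row tibble: `total_attributes`, `unique_names`,
#'   `dictionary_names_used`, `custom_names`,
#'   `attributes_using_custom_names`, `records_touched_by_custom_names`,
#'   `mean_attributes_per_record`.
#' @export
attribute_name_census <- function(corpus, registry) {
  stopifnot(inherits(corpus, "sample_corpus"))
  name <- trimws(corpus$attributes$name)
  uniq <- unique(name)
  cls <- classify_name(registry, uniq)
  is_custom <- name %in% uniq[cls == "custom"]
  tibble::tibble(
    total_attributes = length(name),
    unique_names = length(uniq),
    dictionary_names_used = sum(cls == "dictionary"),
    custom_names = sum(cls == "custom"),
    attributes_using_custom_names = sum(is_custom),
    records_touched_by_custom_names =
      dplyr::n_distinct(corpus$attributes$accession[is_custom]),
    mean_attributes_per_record =
      length(name) / max(1L, nrow(corpus$records)))
}

#' Intersect two repository corpora
#'
#' Compares two corpora by exact accession equality -- the mechanism by
#' which records mirrored between repositories are identified -- and
#' also intersects their sets of unique (trimmed) attribute names.
#'
#' @param x,y Two [sample_corpus()] objects.
#' @return A list: `shared_accessions`, `n_x`, `n_y`, `n_shared`,
#'   `shared_attribute_names`.
#' @export
intersect_repositories <- function(x, y) {
  stopifnot(inherits(x, "sample_corpus"), inherits(y, "sample_corpus"))
  shared <- intersect(x$records$accession, y$records$accession)
  list(shared_accessions = sort(shared),
       n_x = nrow(x$records),
       n_y = nrow(y$records),
       n_shared = length(shared),
       shared_attribute_names =
         sort(intersect(unique(trimws(x$attributes$name)),
                        unique(trimws(y$attributes$name)))))
}

#' Census of term-source URIs
#'
#' Collects the distinct ontology URIs appearing in `Term Source REF`
#' fields and classifies each syntactically: `well_formed` when it has
#' a URI scheme followed by a colon, `malformed` otherwise (catching,
#' e.g., `http//...` with the colon missing). URIs differing only by a
#' trailing slash are distinct entries.
#'
#' @param corpus A [sample_corpus()].
#' @return A tibble `uri`, `n`, `class`, sorted by descending count.
#' @export
term_source_uri_census <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  uri <- corpus$attributes$term_source_ref
  uri <- uri[!is.na(uri) & nzchar(trimws(uri))]
  if (!length(uri)) {
    return(tibble::tibble(uri = character(), n = integer(),
                          class = character()))
  }
  tibble::tibble(uri = uri) |>
    dplyr::count(.data$uri, name = "n") |>
    dplyr::mutate(class = ifelse(
      grepl("^[A-Za-z][A-Za-z0-9+.-]*:", .data$uri),
      "well_formed", "malformed")) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$uri)
}

#' Load a concept-group table
#'
#' Concept groups are curated sets of attribute names that describe the
#' same aspect of a sample (age, weight, geographic location, ...),
#' typically distilled from name clusters. The shipped fixture is
#' `metaqc_file("concept_groups.tsv")`; the file is editable data, not
#' code.
#'
#' @param path Path to a two-column TSV (`concept`, `attribute_name`).
#' @return A tibble `concept`, `attribute_name`.
#' @export
load_concept_groups <- function(path = metaqc_file("concept_groups.tsv")) {
  g <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                  colClasses = "character")
  stopifnot(all(c("concept", "attribute_name") %in% names(g)))
  tibble::as_tibble(g[c("concept", "attribute_name")])
}

#' Count records touched by each concept group
#'
#' A record counts once per concept when it contains at least one
#' attribute whose (trimmed) name belongs to the group, however many
#' member names it uses. Groups are expected to be disjoint; a name
#' assigned to several concepts triggers a warning.
#'
#' @param corpus A [sample_corpus()].
#' @param groups A concept-group tibble from [load_concept_groups()].
#' @return A tibble `concept`, `n_records`, in group order.
#' @export
concept_record_counts <- function(corpus, groups = load_concept_groups()) {
  stopifnot(inherits(corpus, "sample_corpus"))
  overlap <- groups$attribute_name[duplicated(groups$attribute_name)]
  if (length(overlap)) {
    warning("attribute names in more than one concept group: ",
            paste(unique(overlap), collapse = ", "), call. = FALSE)
  }
  name <- trimws(corpus$attributes$name)
  concepts <- unique(groups$concept)
  n <- vapply(concepts, function(cc) {
    members <- groups$attribute_name[groups$concept == cc]
    dplyr::n_distinct(corpus$attributes$accession[name %in% members])
  }, integer(1))
  tibble::tibble(concept = concepts, n_records = unname(n))
}

#' Load a name-category table
#'
#' Categories of frequently used attribute names (biomedical
#' characteristic, date, geographic location, measurement, identifier,
#' textual description). Shipped fixture:
#' `metaqc_file("name_categories.tsv")`.
#'
#' @param path Path to a two-column TSV (`category`, `attribute_name`).
#' @return A tibble `category`, `attribute_name`.
#' @export
load_name_categories <- function(path = metaqc_file("name_categories.tsv")) {
  g <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                  colClasses = "character")
  stopifnot(all(c("category", "attribute_name") %in% names(g)))
  tibble::as_tibble(g[c("category", "attribute_name")])
}

#' Categorise the most-used attribute names
#'
#' Ranks names by how many records use them (ties broken
#' lexicographically), keeps the top `n`, and joins the editable
#' category table; names without a category are reported as
#' `"unmapped"`.
#'
#' @param corpus A [sample_corpus()].
#' @param categories A category tibble from [load_name_categories()].
#' @param n How many top names to keep.
#' @return A tibble `name`, `n_records`, `n_occurrences`, `category`.
#' @export
categorize_top_names <- function(corpus, categories = load_name_categories(),
                                 n = 50L) {
  ranked <- head(rank_names_by_use(corpus), n)
  ranked$category <- categories$category[
    match(ranked$name, categories$attribute_name)]
  ranked$category[is.na(ranked$category)] <- "unmapped"
  ranked
}
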