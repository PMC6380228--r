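#' Load a spec registry from a profile configuration file
#'
#' A spec registry is the declarative dictionary that drives validation:
#' attribute specifications (each with exactly one value class), the
#' closed value sets they reference, and package definitions (sets of
#' required and optional attribute names, with the `Generic` package
#' requiring nothing). The package ships two profiles:
#' `metaqc_file("ncbi_profile.yaml")`, encoding the 452-name NCBI
#' BioSample attribute dictionary (4 boolean, 4 integer, 11 timestamp,
#' 32 value-set and 9 ontology-term attributes; the rest carry no
#' machine-testable value grammar and are marked `unchecked`), and
#' `metaqc_file("ebi_profile.yaml")` with the three EBI named attributes
#' (`Organism`, `Material`, `Sex`).
#'
#' The profile file is YAML with four sections: `attributes` (each entry
#' has `name`, `class`, optional `harmonized_name`, and a `value_set` or
#' `ontology` reference as its class requires), `value_sets`,
#' `packages`, and a `profile` label (`NCBI` or `EBI`). Loading is
#' deterministic and validates the schema: an unknown value class, a
#' value-set spec without a value set, a dangling value-set reference,
#' or a duplicated canonical name raises an error naming the offending
#' field.
#'
#' @param path Path to a profile YAML file.
#' @return A `spec_registry` object.
#' @export
load_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || !is.list(doc) || is.null(doc$attributes)) {
    stop("not a profile file (no 'attributes' section): ", path, call. = FALSE)
  }
  profile <- doc$profile %||% "NCBI"
  if (!profile %in% c("NCBI", "EBI")) {
    stop("profile: must be NCBI or EBI, got '", profile, "'", call. = FALSE)
  }
  classes <- c("boolean", "integer", "timestamp", "value_set",
               "ontology_term", "unchecked")
  value_sets <- doc$value_sets %||% list()
  value_sets <- lapply(value_sets, function(v) as.character(unlist(v)))

  specs <- lapply(seq_along(doc$attributes), function(i) {
    a <- doc$attributes[[i]]
    where <- sprintf("attributes[%d]", i)
    if (is.null(a$name) || !nzchar(trimws(a$name))) {
      stop(where, ": missing name", call. = FALSE)
    }
    if (is.null(a$class) || !a$class %in% classes) {
      stop(where, " (", a$name, "): unknown value class '",
           a$class %||% "", "'", call. = FALSE)
    }
    if (a$class == "value_set") {
      if (is.null(a$value_set)) {
        stop(where, " (", a$name, "): value_set class needs a value_set",
             call. = FALSE)
      }
      if (is.null(value_sets[[a$value_set]]) ||
          !length(value_sets[[a$value_set]])) {
        stop(where, " (", a$name, "): value set '", a$value_set,
             "' is missing or empty", call. = FALSE)
      }
    }
    if (a$class == "ontology_term" &&
        (is.null(a$ontology) || !nzchar(a$ontology))) {
      stop(where, " (", a$name, "): ontology_term class needs an ontology",
           call. = FALSE)
    }
    tibble::tibble(canonical_name = a$name,
                   harmonized_name = a$harmonized_name %||% NA_character_,
                   value_class = a$class,
                   value_set = a$value_set %||% NA_character_,
                   ontology = a$ontology %||% NA_character_)
  })
  specs <- dplyr::bind_rows(specs)
  dup <- specs$canonical_name[duplicated(specs$canonical_name)]
  if (length(dup)) {
    stop("duplicate canonical names in attributes: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  packages <- lapply(seq_along(doc$packages %||% list()), function(i) {
    p <- doc$packages[[i]]
    req <- as.character(unlist(p$required %||% list()))
    opt <- as.character(unlist(p$optional %||% list()))
    both <- intersect(req, opt)
    if (length(both)) {
      stop(sprintf("packages[%d] (%s): attributes both required and optional: %s",
                   i, p$name %||% "?", paste(both, collapse = ", ")),
           call. = FALSE)
    }
    list(name = p$name, required = req, optional = opt)
  })
  names(packages) <- vapply(packages, `[[`, "", "name")

  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(specs))) {
    index[[specs$canonical_name[[i]]]] <- i
    h <- specs$harmonized_name[[i]]
    if (!is.na(h) && is.null(index[[h]])) index[[h]] <- i
  }
  structure(list(profile = profile, specs = specs, value_sets = value_sets,
                 packages = packages, index = index),
            class = "spec_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spec_registry <- function(x, ...) {
  cat(sprintf("<spec_registry> %s profile: %d attribute specs, %d value sets, %d packages\n",
              x$profile, nrow(x$specs), length(x$value_sets),
              length(x$packages)))
  print(table(x$specs$value_class))
  invisible(x)
}

#' Look up the attribute specification for a name
#'
#' Matching trims surrounding whitespace and is otherwise case-sensitive
#' and exact, against both the canonical and the harmonized spelling of
#' each dictionary entry: the name census treats case variants as
#' syntactically distinct custom names, so `"Altitude (m)"` does not
#' resolve to the dictionary's `altitude`.
#'
#' @param registry A `spec_registry` from [load_registry()].
#' @param name A single attribute name.
#' @return A one-row tibble (columns `canonical_name`, `harmonized_name`,
#'   `value_class`, `value_set`, `ontology`, plus `values`, the resolved
#'   value set as a character vector), or `NULL` when the name is not in
#'   the dictionary.
#' @export
lookup_spec <- function(registry, name) {
  stopifnot(inherits(registry, "spec_registry"), length(name) == 1L)
  name <- trimws(name)
  if (is.na(name) || !nzchar(name)) return(NULL)
  i <- registry$index[[name]]
  if (is.null(i)) return(NULL)
  spec <- registry$specs[i, ]
  spec$values <- list(if (!is.na(spec$value_set))
    registry$value_sets[[spec$value_set]] else character())
  spec
}

#' Classify attribute names as dictionary or custom
#'
#' A name is `dictionary` exactly when [lookup_spec()] finds a
#' specification for it; everything else -- including case variants and
#' decorated forms of dictionary names -- is `custom`, mirroring how the
#' census separates repository-specified from user-specified names.
#'
#' @param registry A `spec_registry`.
#' @param names Character vector of attribute names.
#' @return Character vector, `"dictionary"` or `"custom"`, same length
#'   as `names`.
#' @export
classify_name <- function(registry, names) {
  stopifnot(inherits(registry, "spec_registry"))
  hit <- spec_row(registry, names)
  ifelse(is.na(hit), "custom", "dictionary")
}

# vectorised index lookup: row number into registry$specs, NA when custom
spec_row <- function(registry, names) {
  vapply(trimws(names), function(n) {
    if (!nzchar(n)) return(NA_integer_)
    i <- registry$index[[n]]
    if (is.null(i)) NA_integer_ else as.integer(i)
  }, integer(1), USE.NAMES = FALSE)
}
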