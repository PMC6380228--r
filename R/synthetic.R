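#' Typo model for fabricated attribute-name variants
#'
#' Describes how submitters mangle dictionary attribute names: a number
#' of single-character edits (insertion, deletion, or substitution) and
#' an optional decoration affix of the kind seen in the wild
#' (`weight_kg`, `weight (kg)`, `Weight..kg.`).
#'
#' @param edit_rate Number of single-character edits per variant.
#' @param decorations Candidate affixes appended to the name; use
#'   `character()` for none.
#' @param decoration_prob Probability that a variant receives one
#'   decoration.
#' @return A list of class `typo_model`.
#' @export
typo_model <- function(edit_rate = 1L,
                       decorations = c("_kg", " (kg)", "..kg.", "_m",
                                       " (years)", "_1", "2", " µm"),
                       decoration_prob = 0.5) {
  stopifnot(edit_rate >= 0, decoration_prob >= 0, decoration_prob <= 1)
  structure(list(edit_rate = as.integer(edit_rate),
                 decorations = as.character(decorations),
                 decoration_prob = decoration_prob),
            class = "typo_model")
}

#' Fabricate a variant of an attribute name
#'
#' Applies `edit_rate` random single-character edits and (with the
#' model's probability) one decoration affix. The Levenshtein distance
#' from the original is therefore at most `edit_rate` plus the length
#' of the longest decoration. With `edit_rate = 0` and no decorations
#' the name comes back unchanged.
#'
#' @param name A non-empty name.
#' @param model A [typo_model()].
#' @param seed Optional seed making the draw reproducible.
#' @return The variant name.
#' @export
perturb_name <- function(name, model = typo_model(), seed = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  alphabet <- c(letters, "_", " ", ".")
  out <- name
  for (i in seq_len(model$edit_rate)) {
    op <- sample(c("insert", "delete", "substitute"), 1L)
    k <- nchar(out)
    if (op == "delete" && k > 1L) {
      p <- sample.int(k, 1L)
      out <- paste0(substr(out, 1L, p - 1L), substr(out, p + 1L, k))
    } else if (op == "insert") {
      p <- sample.int(k + 1L, 1L) - 1L
      out <- paste0(substr(out, 1L, p), sample(alphabet, 1L),
                    substr(out, p + 1L, k))
    } else {
      p <- sample.int(k, 1L)
      out <- paste0(substr(out, 1L, p - 1L), sample(alphabet, 1L),
                    substr(out, p + 1L, k))
    }
  }
  if (length(model$decorations) && runif(1L) < model$decoration_prob) {
    out <- paste0(out, sample(model$decorations, 1L))
  }
  out
}

#' Configuration for a synthetic corpus
#'
#' Encodes the statistical structure of a repository snapshot as exact
#' composition targets: fractions are converted to integer counts by
#' largest-remainder rounding, never by independent draws, so the
#' ground-truth ledger holds exact counts known a priori and report
#' recovery can be tested as equality.
#'
#' Defaults emulate the repository conditions the reports are designed
#' around: an NCBI-style mix dominated by the Generic package (85%),
#' submissions concentrated in recent years, per-class validity
#' fractions of 0.27 (boolean), 0.74 (integer), 0.74 (timestamp), 0.92
#' (value set) and 0.32 (ontology term), and 15% of free-form attribute
#' occurrences using submitter-invented custom names. For the EBI
#' dialect the checked classes are the named attributes (`Organism`,
#' `Material`, `Sex`), the default package mix is 60% unpackaged, and
#' records carry term-source URIs drawn from `term_source_uri_pool`.
#'
#' @param n_records Number of records.
#' @param repository `"NCBI"` or `"EBI"`.
#' @param package_mix Named fractions over package labels (must sum to
#'   1); the label `"Unpackaged"` means no package reference (EBI).
#' @param year_histogram Named fractions over submission years (NCBI
#'   dialect only; SampleTab carries no dates).
#' @param per_class_validity Named fractions of well-specified values
#'   per checked value class.
#' @param n_unchecked_per_record Free-form attributes per record; the
#'   default of 7, together with the typed attributes, gives the mean
#'   of 12 (NCBI) / 10 (EBI) attributes per record seen in the
#'   repositories.
#' @param custom_name_rate Fraction of *all* attribute occurrences that
#'   use custom (non-dictionary) names; realised within the free-form
#'   attributes, so it must not exceed their share of the record.
#' @param n_custom_variants Size of the planted custom-name pool.
#' @param typo_model A [typo_model()] for fabricating those names.
#' @param term_source_uri_pool URIs attached to EBI `Organism`
#'   attributes as `Term Source REF`.
#' @param seed Integer seed; every random choice derives from it.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_records,
                          repository = c("NCBI", "EBI"),
                          package_mix = NULL,
                          year_histogram = NULL,
                          per_class_validity = NULL,
                          n_unchecked_per_record = 7L,
                          custom_name_rate = 0.15,
                          n_custom_variants = 25L,
                          typo_model = NULL,
                          term_source_uri_pool = NULL,
                          seed = 1L) {
  repository <- match.arg(repository)
  if (is.null(package_mix)) {
    package_mix <- if (repository == "NCBI") {
      c(Generic = 0.85, "Pathogen.cl.1.0" = 0.04, "Human.1.0" = 0.04,
        "Microbe.1.0" = 0.03, "Plant.1.0" = 0.02,
        "Metagenome.environmental.1.0" = 0.02)
    } else {
      c(Unpackaged = 0.60, Generic = 0.16,
        "Metagenome.environmental.1.0" = 0.04, "Human.1.0" = 0.08,
        "Pathogen.cl.1.0" = 0.06, "Microbe.1.0" = 0.06)
    }
  }
  if (is.null(year_histogram)) {
    year_histogram <- c("2009" = 0.01, "2010" = 0.02, "2011" = 0.04,
                        "2012" = 0.06, "2013" = 0.08, "2014" = 0.13,
                        "2015" = 0.18, "2016" = 0.23, "2017" = 0.25)
  }
  if (is.null(per_class_validity)) {
    per_class_validity <- if (repository == "NCBI") {
      c(boolean = 0.27, integer = 0.74, timestamp = 0.74,
        value_set = 0.92, ontology_term = 0.32)
    } else {
      c(value_set = 0.90, ontology_term = 0.87)
    }
  }
  if (is.null(typo_model)) typo_model <- default_typo_model()
  if (is.null(term_source_uri_pool)) {
    term_source_uri_pool <- c(
      "http://purl.obolibrary.org/obo/ncbitaxon.owl",
      "https://www.ebi.ac.uk/ols/ontologies/ncbitaxon",
      "http://bioportal.bioontology.org/ontologies/NCBITAXON")
  }
  stopifnot(n_records >= 0,
            abs(sum(package_mix) - 1) < 1e-8,
            all(package_mix >= 0),
            abs(sum(year_histogram) - 1) < 1e-8,
            all(per_class_validity >= 0 & per_class_validity <= 1),
            n_unchecked_per_record >= 0,
            custom_name_rate >= 0 && custom_name_rate <= 1,
            n_custom_variants >= 1)
  allowed <- if (repository == "NCBI") {
    c("boolean", "integer", "timestamp", "value_set", "ontology_term")
  } else {
    c("value_set", "ontology_term")
  }
  extra <- setdiff(names(per_class_validity), allowed)
  if (length(extra)) {
    stop("per_class_validity names a class with no attributes in the ",
         repository, " profile: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), repository = repository,
                 package_mix = package_mix, year_histogram = year_histogram,
                 per_class_validity = per_class_validity,
                 n_unchecked_per_record = as.integer(n_unchecked_per_record),
                 custom_name_rate = custom_name_rate,
                 n_custom_variants = as.integer(n_custom_variants),
                 typo_model = typo_model,
                 term_source_uri_pool = term_source_uri_pool,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

default_typo_model <- function() typo_model()

# largest-remainder apportionment of n into named integer counts
exact_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_by_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_by_rem[seq_len(short)]] <- counts[order_by_rem[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

# n validity flags with an exact count of TRUEs: floor(frac * n + 0.5)
validity_flags <- function(frac, n) {
  k <- min(n, floor(frac * n + 0.5))
  sample(rep(c(TRUE, FALSE), c(k, n - k)))
}

.organism_pool <- data.frame(
  name = c("Homo sapiens", "Mus musculus", "Escherichia coli",
           "Arabidopsis thaliana", "Danio rerio", "Bos taurus"),
  taxid = c("9606", "10090", "562", "3702", "7955", "9913"),
  stringsAsFactors = FALSE)

.owner_pool <- c("EBI", "Broad Institute", "Wellcome Sanger Institute",
                 "DOE Joint Genome Institute", "University Lab A",
                 "University Lab B", "Hospital Biobank C")

.pools <- list(
  boolean_valid = c("true", "false", "TRUE", "FALSE", "True", "False"),
  # observed-in-the-wild invalid booleans; none lowercases to true/false
  boolean_invalid = c("Yes", "No", "Y", "N", "0", "1", "--", "never",
                      "never smoker", "non smoker", "nonsmoker", "ex-smoker",
                      "Ex smoker", "former-smoker", "Former", "current smoker",
                      "f", "T"),
  integer_invalid = c("3.5", "N/A", "Mus musculus", "NO", "e;N/A",
                      "Fluoxetine", "Simvastatin",
                      "Insulin glargine injectable solution", "12 years",
                      "1,000", "1e5", "unknown", "not determined", "-"),
  # malformed shapes: ranges, slashes, free text, bad components
  timestamp_invalid = c("1800/2014", "Jan-Feb 2009", "no description",
                        "unspecified", "2000/11/20", "20 Nov 2000",
                        "Nov 2000", "2000-13-01", "2000-1-1", "32-Jan-2000",
                        "00-Jan-2000", "2000-11-20T25:00:00", "15-Janu-2000",
                        "n/a", "missing", "late 2014", "Marc-2000"),
  free_text = c("not applicable", "wild type", "collected in the field",
                "liver biopsy", "pool of 10 animals", "see notes", "control",
                "treated", "unknown", "baseline", "passage 3",
                "frozen at -80C", "replicate 2", "mixed culture"))

random_valid_timestamp <- function(n) {
  fmt <- sample(6L, n, replace = TRUE)
  year <- sample(1990:2017, n, replace = TRUE)
  mon <- sample(12L, n, replace = TRUE)
  day <- sample(28L, n, replace = TRUE)
  hh <- sample(0:23, n, replace = TRUE)
  mi <- sample(0:59, n, replace = TRUE)
  ss <- sample(0:59, n, replace = TRUE)
  mmm <- .months[mon]
  out <- character(n)
  out[fmt == 1L] <- sprintf("%d-%s-%04d", day[fmt == 1L], mmm[fmt == 1L],
                            year[fmt == 1L])
  out[fmt == 2L] <- sprintf("%s-%04d", mmm[fmt == 2L], year[fmt == 2L])
  out[fmt == 3L] <- sprintf("%04d", year[fmt == 3L])
  out[fmt == 4L] <- sprintf("%04d-%02d", year[fmt == 4L], mon[fmt == 4L])
  out[fmt == 5L] <- sprintf("%04d-%02d-%02d", year[fmt == 5L], mon[fmt == 5L],
                            day[fmt == 5L])
  out[fmt == 6L] <- sprintf("%04d-%02d-%02dT%02d:%02d:%02d", year[fmt == 6L],
                            mon[fmt == 6L], day[fmt == 6L], hh[fmt == 6L],
                            mi[fmt == 6L], ss[fmt == 6L])
  out
}

random_case <- function(x) {
  how <- sample(4L, length(x), replace = TRUE)
  out <- x
  out[how == 2L] <- toupper(x[how == 2L])
  out[how == 3L] <- tolower(x[how == 3L])
  cap <- how == 4L
  out[cap] <- paste0(toupper(substr(x[cap], 1, 1)), substring(x[cap], 2))
  out
}

# corrupt a value-set member so it can no longer match any member
# case-insensitively: internal-space insertion, letter doubling, or a
# one-character typo, with membership re-checked after corruption
corrupt_member <- function(member, set_lower) {
  for (attempt in seq_len(25L)) {
    m <- member
    k <- nchar(m)
    op <- sample(4L, 1L)
    if (op == 1L && k > 2L) {            # internal space: "mal e"
      p <- sample(seq_len(k - 1L)[-1L], 1L)
      m <- paste0(substr(m, 1, p - 1L), " ", substr(m, p, k))
    } else if (op == 2L) {               # doubled letter: "makle"-ish
      p <- sample.int(k, 1L)
      m <- paste0(substr(m, 1, p), substr(m, p, k))
    } else if (op == 3L && k > 2L) {     # dropped letter: "femLE"-ish
      p <- sample.int(k, 1L)
      m <- paste0(substr(m, 1, p - 1L), substr(m, p + 1L, k))
    } else {                             # truncation: "m", "f"
      m <- substr(m, 1, max(1L, sample.int(max(1L, k - 1L), 1L)))
    }
    if (nzchar(trimws(m)) && !(tolower(trimws(m)) %in% set_lower)) return(m)
  }
  paste0(member, " ###")
}

load_term_pools <- function(path) {
  idx <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = "character")
  labels <- split(idx$preferred_label, idx$ontology)
  keys <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(idx))) {
    syns <- strsplit(idx$synonyms[[i]], "|", fixed = TRUE)[[1]]
    for (k in tolower(c(idx$preferred_label[[i]], idx$term_id[[i]],
                        trimws(syns[nzchar(trimws(syns))])))) {
      keys[[k]] <- TRUE
    }
  }
  ids <- split(idx$term_id, idx$ontology)
  list(labels = labels, ids = ids, keys = keys)
}

# corrupt an ontology label into a guaranteed non-matching value:
# underscores for spaces, or a trailing qualifier, as seen in the wild
corrupt_label <- function(label, keys) {
  cands <- c(gsub(" ", "_", label, fixed = TRUE),
             paste0(label, "_4"),
             paste0(gsub(" ", "_", tolower(label), fixed = TRUE), "_positive"),
             paste0(label, " isolate p105"))
  for (m in sample(cands)) {
    if (is.null(keys[[tolower(m)]])) return(m)
  }
  paste0(label, " ###")
}

#' Generate a synthetic corpus with an exact ground-truth ledger
#'
#' Builds `n_records` sample records in the configured repository
#' dialect. Every composition target of the configuration -- package
#' mix, year histogram, per-class validity fractions, custom-name rate
#' -- is realised as an exact integer count (largest-remainder
#' rounding), and every generated attribute is covered by exactly one
#' ledger row stating its intended value class, validity, and (for
#' custom name variants) the dictionary name it was derived from.
#' Quality reports run on the corpus must therefore equal the ledger
#' exactly; that closure is the package's core self-test.
#'
#' Invalid values are drawn from class-aware pools of realistic
#' mistakes (boolean synonyms like `Yes`/`N`/`never smoker`; malformed
#' dates like `1800/2014`; value-set members corrupted by internal
#' spaces or typos; ontology labels broken by underscores), constructed
#' so that a correct validator can never accept them.
#'
#' @param config A [corpus_config()].
#' @param registry Spec registry for attribute-name sampling; defaults
#'   to the profile matching the configured repository.
#' @param term_index_path Term index backing valid/invalid ontology
#'   values.
#' @return A list: `corpus` (a [sample_corpus()]) and `ledger` (list of
#'   `attributes` -- one row per generated attribute occurrence, with
#'   `value_class`, `valid`, `source_name` -- and `records` with the
#'   planted `package` and `year` per record).
#' @export
generate_corpus <- function(config,
                            registry = NULL,
                            term_index_path = metaqc_file("term_index.tsv")) {
  stopifnot(inherits(config, "corpus_config"))
  if (is.null(registry)) {
    registry <- load_registry(metaqc_file(
      if (config$repository == "NCBI") "ncbi_profile.yaml"
      else "ebi_profile.yaml"))
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_records
  ebi <- config$repository == "EBI"
  if (n == 0L) {
    return(list(corpus = sample_corpus(),
                ledger = list(attributes = ledger_prototype(),
                              records = tibble::tibble(
                                accession = character(),
                                package = character(),
                                year = character()))))
  }
  accession <- if (ebi) sprintf("SAMEA%07d", seq_len(n))
               else sprintf("SAMN%08d", seq_len(n))

  package <- sample(rep(names(config$package_mix),
                        exact_counts(config$package_mix, n)))
  year <- sample(rep(names(config$year_histogram),
                     exact_counts(config$year_histogram, n)))
  sub_date <- sprintf("%s-%02d-%02d", year, sample(12L, n, replace = TRUE),
                      sample(28L, n, replace = TRUE))
  org_i <- sample(nrow(.organism_pool), n, replace = TRUE)

  pools <- load_term_pools(term_index_path)
  specs <- registry$specs
  blocks <- list()
  add_block <- function(ord, name, value, value_class, valid,
                        source_name = NA_character_,
                        term_source_ref = NA_character_,
                        term_source_id = NA_character_) {
    blocks[[length(blocks) + 1L]] <<- tibble::tibble(
      accession = accession, ord = ord, name = name, value = value,
      term_source_ref = term_source_ref, term_source_id = term_source_id,
      value_class = value_class, valid = valid, source_name = source_name)
  }

  classes <- names(config$per_class_validity)
  class_ord <- stats::setNames(seq_along(classes), classes)

  for (cls in classes) {
    valid <- validity_flags(config$per_class_validity[[cls]], n)
    if (!ebi) {
      cand <- specs$canonical_name[specs$value_class == cls]
      name <- sample(cand, n, replace = TRUE)
    }
    if (cls == "boolean") {
      value <- ifelse(valid,
                      sample(.pools$boolean_valid, n, replace = TRUE),
                      sample(.pools$boolean_invalid, n, replace = TRUE))
      add_block(class_ord[[cls]], name, value, cls, valid)
    } else if (cls == "integer") {
      value <- ifelse(valid,
                      as.character(sample.int(1000000L, n, replace = TRUE) - 1L),
                      sample(.pools$integer_invalid, n, replace = TRUE))
      neg <- valid & runif(n) < 0.1
      value[neg] <- paste0("-", value[neg])
      add_block(class_ord[[cls]], name, value, cls, valid)
    } else if (cls == "timestamp") {
      value <- ifelse(valid, random_valid_timestamp(n),
                      sample(.pools$timestamp_invalid, n, replace = TRUE))
      add_block(class_ord[[cls]], name, value, cls, valid)
    } else if (cls == "value_set") {
      if (ebi) name <- rep("Sex", n)
      set_of <- specs$value_set[match(name, specs$canonical_name)]
      value <- character(n)
      for (s in unique(set_of)) {
        members <- registry$value_sets[[s]]
        rows <- which(set_of == s)
        pick <- sample(members, length(rows), replace = TRUE)
        ok <- valid[rows]
        value[rows[ok]] <- random_case(pick[ok])
        value[rows[!ok]] <- vapply(pick[!ok], corrupt_member,
                                   character(1),
                                   set_lower = tolower(members))
      }
      add_block(class_ord[[cls]], name, value, cls, valid)
    } else if (cls == "ontology_term") {
      if (ebi) {
        # two named ontology-term attributes per record, each with the
        # configured validity fraction
        for (nm in c("Organism", "Material")) {
          onto <- specs$ontology[match(nm, specs$canonical_name)]
          pool_onto <- if (onto == "ANY") "EFO" else onto
          labels <- pools$labels[[pool_onto]]
          v2 <- validity_flags(config$per_class_validity[[cls]], n)
          pick <- sample(labels, n, replace = TRUE)
          value <- ifelse(v2, pick,
                          vapply(pick, corrupt_label, character(1),
                                 keys = pools$keys))
          tsr <- tsi <- rep(NA_character_, n)
          if (nm == "Organism") {
            tsr <- sample(config$term_source_uri_pool, n, replace = TRUE)
            tsi <- paste0("NCBITaxon:",
                          sample(9000:99999, n, replace = TRUE))
          }
          add_block(class_ord[[cls]] + (nm == "Material") * 0.5,
                    rep(nm, n), value, cls, v2,
                    term_source_ref = tsr, term_source_id = tsi)
        }
      } else {
        onto_of <- specs$ontology[match(name, specs$canonical_name)]
        value <- character(n)
        for (o in unique(onto_of)) {
          rows <- which(onto_of == o)
          labels <- pools$labels[[o]]
          if (is.null(labels)) {
            stop("term index has no terms for ontology ", o, call. = FALSE)
          }
          pick <- sample(labels, length(rows), replace = TRUE)
          ok <- valid[rows]
          value[rows[ok]] <- pick[ok]
          value[rows[!ok]] <- vapply(pick[!ok], corrupt_label, character(1),
                                     keys = pools$keys)
        }
        add_block(class_ord[[cls]], name, value, cls, valid)
      }
    }
  }

  # free-form attributes: dictionary names without a value grammar, plus
  # planted custom-name variants
  k <- config$n_unchecked_per_record
  if (k > 0L) {
    unchecked_names <- specs$canonical_name[specs$value_class == "unchecked"]
    if (ebi) {
      # the EBI profile has no unchecked dictionary entries; free-form
      # names are all custom there, sourced from the NCBI dictionary
      ncbi_reg <- load_registry(metaqc_file("ncbi_profile.yaml"))
      unchecked_names <- ncbi_reg$specs$canonical_name[
        ncbi_reg$specs$value_class == "unchecked"]
    }
    m <- n * k
    sources <- sample(unchecked_names, config$n_custom_variants,
                      replace = config$n_custom_variants > length(unchecked_names))
    variants <- character(length(sources))
    for (i in seq_along(sources)) {
      repeat {
        v <- perturb_name(sources[[i]], config$typo_model)
        # trim-stable and distinct from every dictionary name, so the
        # trimmed name census sees exactly these variants as custom
        in_dict <- !is.null(registry$index[[v]]) ||
          (ebi && v %in% unchecked_names)
        if (identical(v, trimws(v)) && nzchar(v) && !in_dict &&
            !v %in% variants) break
      }
      variants[[i]] <- v
    }
    m_total <- m + sum(vapply(blocks, nrow, integer(1)))
    n_custom <- floor(config$custom_name_rate * m_total + 0.5)
    if (n_custom > m) {
      stop("custom_name_rate ", config$custom_name_rate, " needs ",
           n_custom, " custom attributes but only ", m,
           " free-form attributes are generated; raise ",
           "n_unchecked_per_record", call. = FALSE)
    }
    is_custom <- sample(rep(c(TRUE, FALSE), c(n_custom, m - n_custom)))
    pool_idx <- sample(length(variants), m, replace = TRUE)
    name <- ifelse(is_custom, variants[pool_idx],
                   sample(unchecked_names, m, replace = TRUE))
    src <- ifelse(is_custom, sources[pool_idx], NA_character_)
    cls_lab <- ifelse(is_custom, "custom", "unchecked")
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      accession = rep(accession, each = k),
      ord = 50 + rep(seq_len(k), times = n),
      name = name,
      value = sample(.pools$free_text, m, replace = TRUE),
      term_source_ref = NA_character_, term_source_id = NA_character_,
      value_class = cls_lab, valid = NA, source_name = src)
  }

  if (ebi) {
    packaged <- package != "Unpackaged"
    if (any(packaged)) {
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        accession = accession[packaged], ord = 99,
        name = "package", value = package[packaged],
        term_source_ref = NA_character_, term_source_id = NA_character_,
        value_class = "package_ref", valid = NA, source_name = NA_character_)
    }
  }

  attrs <- dplyr::bind_rows(blocks)
  attrs <- attrs[order(match(attrs$accession, accession), attrs$ord), ]
  attrs$position <- stats::ave(rep(1L, nrow(attrs)), attrs$accession,
                               FUN = seq_along)

  org_name <- .organism_pool$name[org_i]
  org_tax <- .organism_pool$taxid[org_i]
  if (ebi) {
    # the record-level organism mirrors the Organism attribute
    first_org <- attrs[attrs$name == "Organism", ]
    first_org <- first_org[!duplicated(first_org$accession), ]
    org_name <- first_org$value[match(accession, first_org$accession)]
    org_tax <- NA_character_
  }
  records <- tibble::tibble(
    record_id = if (ebi) accession else as.character(seq_len(n)),
    accession = accession,
    repository = config$repository,
    title = paste("Sample", seq_len(n)),
    publication_date = if (ebi) NA_character_ else sub_date,
    last_update_date = if (ebi) NA_character_ else sub_date,
    submission_date = if (ebi) NA_character_ else sub_date,
    organism_name = org_name,
    organism_taxon_id = org_tax,
    owner = if (ebi) NA_character_ else
      sample(.owner_pool, n, replace = TRUE),
    package = if (ebi) NA_character_ else package)

  corpus <- sample_corpus(records,
                          attrs[names(empty_attributes())])
  ledger_attrs <- attrs[c("accession", "position", "name", "source_name",
                          "value_class", "valid", "value")]
  list(corpus = corpus,
       ledger = list(attributes = ledger_attrs,
                     records = tibble::tibble(accession = accession,
                                              package = package,
                                              year = if (ebi) NA_character_
                                                     else year)))
}

ledger_prototype <- function() {
  tibble::tibble(accession = character(), position = integer(),
                 name = character(), source_name = character(),
                 value_class = character(), valid = logical(),
                 value = character())
}

#' Generate a pair of corpora with a planted accession overlap
#'
#' Produces one corpus per repository dialect and rewrites the first
#' `n_shared` EBI accessions (after seeded shuffling) to accessions
#' drawn from the NCBI corpus, emulating records mirrored between
#' repositories. The returned ledger component `shared_accessions`
#' holds the exact planted intersection.
#'
#' @param config_ncbi,config_ebi [corpus_config()] objects for the two
#'   sides.
#' @param n_shared Number of shared accessions (at most the smaller
#'   corpus size).
#' @return A list: `ncbi`, `ebi` (each as from [generate_corpus()]),
#'   and `shared_accessions`.
#' @export
generate_corpus_pair <- function(config_ncbi, config_ebi, n_shared = 0L) {
  stopifnot(n_shared <= config_ncbi$n_records,
            n_shared <= config_ebi$n_records)
  x <- generate_corpus(config_ncbi)
  y <- generate_corpus(config_ebi)
  if (n_shared > 0L) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config_ebi$seed + 1L)
    take_ncbi <- sample(x$corpus$records$accession, n_shared)
    replace_ebi <- sample(y$corpus$records$accession, n_shared)
    map <- stats::setNames(take_ncbi, replace_ebi)
    rewrite <- function(acc) {
      hit <- map[acc]
      ifelse(is.na(hit), acc, hit)
    }
    y$corpus$records$accession <- rewrite(y$corpus$records$accession)
    y$corpus$records$record_id <- y$corpus$records$accession
    y$corpus$attributes$accession <- rewrite(y$corpus$attributes$accession)
    y$ledger$attributes$accession <- rewrite(y$ledger$attributes$accession)
    y$ledger$records$accession <- rewrite(y$ledger$records$accession)
    shared <- sort(unname(take_ncbi))
  } else {
    shared <- character()
  }
  list(ncbi = x, ebi = y, shared_accessions = shared)
}
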