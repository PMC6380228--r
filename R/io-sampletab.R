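#' Read an EBI BioSamples SampleTab file
#'
#' SampleTab is a tab-delimited submission format with two sections:
#' Meta-Submission Information (`[MSI]`) and Sample Characteristics
#' Description (`[SCD]`). Only the SCD section -- a header row of column
#' names followed by one row per sample -- carries per-sample metadata,
#' and only it is consumed here; an MSI section is skipped with a log
#' line. A file without an SCD section yields an empty corpus plus a
#' warning in the parse log. A file with no section markers at all is
#' treated as a bare SCD table.
#'
#' Columns map as follows: `Sample Name` becomes the record id (and the
#' accession when no `Sample Accession` column exists), `Sample
#' Accession` the accession, `Sample Description` the title. Every other
#' column is an attribute, in column order, except that `Term Source
#' REF` / `Term Source ID` columns attach to the attribute in the
#' nearest preceding attribute column. Empty cells contribute no
#' attribute. Rows whose field count differs from the header are dropped
#' with a row-level log entry; duplicated accessions are logged and
#' kept. The first `Organism` attribute of a record also populates the
#' record's `organism_name` for convenience.
#'
#' @param path Path to a SampleTab file.
#' @return A [sample_corpus()] with `repository = "EBI"`.
#' @export
read_sampletab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  log <- empty_parse_log()
  note <- function(level, message) {
    log <<- dplyr::bind_rows(log, tibble::tibble(level = level,
                                                 message = message))
  }

  markers <- grepl("^\\[(MSI|SCD)\\]\\s*$", lines)
  if (any(grepl("^\\[MSI\\]\\s*$", lines))) {
    note("info", "MSI section skipped")
  }
  if (any(markers)) {
    scd_at <- which(grepl("^\\[SCD\\]\\s*$", lines))
    if (!length(scd_at)) {
      note("warning", "no SCD section found")
      return(sample_corpus(parse_log = log))
    }
    start <- scd_at[[1L]] + 1L
    nxt <- which(markers & seq_along(lines) > scd_at[[1L]])
    end <- if (length(nxt)) nxt[[1L]] - 1L else length(lines)
    body <- lines[seq(start, length.out = max(0L, end - start + 1L))]
  } else {
    body <- lines
  }
  body <- body[cumsum(nzchar(trimws(body))) > 0L]   # leading blanks
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    note("warning", "SCD section is empty")
    return(sample_corpus(parse_log = log))
  }

  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  special <- c("Sample Name", "Sample Accession", "Sample Description")
  ts_cols <- header %in% c("Term Source REF", "Term Source ID")
  attr_cols <- which(!(header %in% special) & !ts_cols)
  # strip Characteristic[...] / Comment[...] wrappers to the inner name
  attr_names <- sub("^(Characteristic|Comment)\\[(.*)\\]$", "\\2",
                    header[attr_cols])
  # map each term-source column to the nearest preceding attribute column
  owner_of <- function(j) {
    prior <- attr_cols[attr_cols < j]
    if (length(prior)) prior[[length(prior)]] else NA_integer_
  }
  ref_owner <- vapply(which(header == "Term Source REF"), owner_of, integer(1))
  id_owner <- vapply(which(header == "Term Source ID"), owner_of, integer(1))
  if (anyNA(ref_owner) || anyNA(id_owner)) {
    note("error", "Term Source column with no preceding attribute; ignored")
  }
  ref_for <- stats::setNames(which(header == "Term Source REF")[!is.na(ref_owner)],
                             ref_owner[!is.na(ref_owner)])
  id_for <- stats::setNames(which(header == "Term Source ID")[!is.na(id_owner)],
                            id_owner[!is.na(id_owner)])

  # sentinel keeps trailing empty fields, which strsplit() would drop
  rows <- lapply(strsplit(paste0(body[-1L], "\tEOL"), "\t", fixed = TRUE),
                 function(r) r[-length(r)])
  widths <- lengths(rows)
  ragged <- widths != ncol
  if (any(ragged)) {
    note("error", sprintf("row %d has %d fields, expected %d; skipped",
                          which(ragged) + 1L, widths[ragged], ncol))
    rows <- rows[!ragged]
  }
  if (!length(rows)) {
    return(sample_corpus(parse_log = log))
  }
  cells <- do.call(rbind, rows)

  pick <- function(col) {
    if (col %in% header) {
      v <- cells[, match(col, header)]
      ifelse(v == "", NA_character_, v)
    } else rep(NA_character_, nrow(cells))
  }
  name <- pick("Sample Name")
  accession <- pick("Sample Accession")
  accession <- ifelse(is.na(accession), name, accession)
  keep <- !is.na(accession) & accession != ""
  if (any(!keep)) {
    note("error", sprintf("row %d has no accession or sample name; skipped",
                          which(!keep) + 1L))
    cells <- cells[keep, , drop = FALSE]
    name <- name[keep]; accession <- accession[keep]
  }
  if (!nrow(cells)) return(sample_corpus(parse_log = log))
  dup <- sort(unique(accession[duplicated(accession)]))
  if (length(dup)) {
    note("warning", paste0("duplicate accession: ", dup))
  }

  # record-major traversal of the (record x attribute-column) cell grid
  vm <- t(cells[, attr_cols, drop = FALSE])        # rows = attr columns
  sel <- which(vm != "")
  rec_i <- (sel - 1L) %/% nrow(vm) + 1L
  col_i <- (sel - 1L) %% nrow(vm) + 1L
  ts_of <- function(map) {
    j <- map[as.character(attr_cols[col_i])]
    out <- rep(NA_character_, length(sel))
    has <- !is.na(j)
    out[has] <- cells[cbind(rec_i[has], j[has])]
    ifelse(is.na(out) | out == "", NA_character_, out)
  }
  attributes <- if (!length(sel)) empty_attributes() else tibble::tibble(
    accession = accession[rec_i],
    position = as.integer(stats::ave(rep(1L, length(sel)), rec_i,
                                     FUN = seq_along)),
    name = attr_names[col_i],
    value = vm[sel],
    term_source_ref = ts_of(ref_for),
    term_source_id = ts_of(id_for))

  org <- attributes[attributes$name == "Organism", c("accession", "value")]
  org <- org[!duplicated(org$accession), ]
  records <- tibble::tibble(
    record_id = ifelse(is.na(name), accession, name),
    accession = accession,
    repository = "EBI",
    title = pick("Sample Description"),
    publication_date = NA_character_,
    last_update_date = NA_character_,
    submission_date = NA_character_,
    organism_name = org$value[match(accession, org$accession)],
    organism_taxon_id = NA_character_,
    owner = NA_character_,
    package = NA_character_)
  sample_corpus(records, attributes, parse_log = log)
}

#' Write a corpus as a SampleTab SCD section
#'
#' Lays the attribute occurrences out as one tab-delimited table: a
#' `[SCD]` marker, a header (`Sample Name`, `Sample Accession`, optional
#' `Sample Description`, then attribute columns in order of first
#' appearance, each followed by `Term Source REF`/`Term Source ID`
#' columns when any record carries term-source fields for it), and one
#' row per record. Attribute names repeated within a record get one
#' column per occurrence. [read_sampletab()] parses the output back to
#' field-identical records for everything the SCD dialect can represent
#' (it carries no dates, owner, taxon ids, or empty-valued attributes).
#'
#' A name or value containing a tab or newline cannot be represented and
#' raises an error rather than corrupting the table.
#'
#' @param corpus A [sample_corpus()].
#' @param path Output file, or `NULL` to return the text.
#' @return `path` invisibly, or the SampleTab text when `path` is `NULL`.
#' @export
write_sampletab <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "sample_corpus"))
  recs <- corpus$records
  attrs <- corpus$attributes
  bad <- grepl("[\t\n\r]", attrs$name) | grepl("[\t\n\r]", attrs$value)
  if (any(bad)) {
    stop("attribute names/values containing tabs or newlines cannot be ",
         "written as SampleTab (first offender: record ",
         attrs$accession[bad][1L], ")", call. = FALSE)
  }

  # slot = name + occurrence index within the record
  attrs <- attrs[order(match(attrs$accession, recs$accession), attrs$position), ]
  occ <- stats::ave(seq_len(nrow(attrs)),
                    paste0(attrs$accession, "\r", attrs$name),
                    FUN = seq_along)
  slot <- paste0(attrs$name, "\r", occ)
  slots <- unique(slot)
  slot_name <- sub("\r[0-9]+$", "", slots)
  has_ts <- vapply(slots, function(s) {
    rows <- slot == s
    any(!is.na(attrs$term_source_ref[rows])) ||
      any(!is.na(attrs$term_source_id[rows]))
  }, logical(1))

  use_title <- any(!is.na(recs$title))
  blank <- function(x) ifelse(is.na(x), "", x)

  n <- nrow(recs)
  row_of <- match(attrs$accession, recs$accession)
  col_of <- match(slot, slots)
  fill <- function(value) {
    m <- matrix("", n, length(slots))
    m[cbind(row_of, col_of)] <- blank(value)
    m
  }
  values <- fill(attrs$value)
  refs <- fill(attrs$term_source_ref)
  ids <- fill(attrs$term_source_id)

  header <- c("Sample Name", "Sample Accession",
              if (use_title) "Sample Description")
  columns <- c(list(blank(recs$record_id), recs$accession),
               if (use_title) list(blank(recs$title)))
  for (k in seq_along(slots)) {
    header <- c(header, slot_name[[k]],
                if (has_ts[[k]]) c("Term Source REF", "Term Source ID"))
    columns <- c(columns, list(values[, k]),
                 if (has_ts[[k]]) list(refs[, k], ids[, k]))
  }
  body <- do.call(paste, c(columns, sep = "\t"))

  out <- paste0(paste(c("[SCD]", paste(header, collapse = "\t"), body),
                      collapse = "\n"), "\n")
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(path)
}
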