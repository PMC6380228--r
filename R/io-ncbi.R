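#' Read an NCBI BioSample XML dump
#'
#' Parses a `BioSampleSet` document (one `BioSample` element per sample
#' record) into a [sample_corpus()]. The file is consumed in bounded
#' chunks: record elements are cut out of the byte stream as they
#' complete and each batch is handed to the XML parser, so peak parser
#' memory depends on the batch size, not on the corpus size. (Scanning
#' for the record close tag is sound for well-formed XML, where a literal
#' `</BioSample>` cannot occur inside text content.)
#'
#' Field names and values are kept verbatim -- no trimming, no case
#' folding -- because downstream censuses count syntactically distinct
#' strings. A `BioSample` element without an accession is skipped and
#' recorded in the parse log; parsing continues. Duplicated accessions
#' are likewise logged but kept.
#'
#' @param path Path to a BioSample XML file.
#' @param callback Optional `function(corpus_batch)` invoked once per
#'   parsed batch. When supplied, batches are not accumulated and the
#'   function returns (invisibly) only the total record count, which
#'   keeps memory use flat for arbitrarily large dumps.
#' @param chunk_records Number of records per parsed batch.
#' @return A [sample_corpus()] with `repository = "NCBI"`, or the record
#'   count when `callback` is given.
#' @export
read_biosample_xml <- function(path, callback = NULL, chunk_records = 2000L) {
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  buffer <- ""
  offset <- 0L        # bytes consumed before `buffer`
  pending <- character()
  batches <- list()
  logs <- list()
  total <- 0L
  seen_acc <- new.env(parent = emptyenv())

  flush_pending <- function(force = FALSE) {
    while (length(pending) >= chunk_records || (force && length(pending))) {
      take <- head(pending, chunk_records)
      pending <<- pending[-seq_along(take)]
      batch <- parse_biosample_elements(take, offset)
      logs[[length(logs) + 1L]] <<- batch$log
      total <<- total + nrow(batch$records)
      for (a in batch$records$accession) {
        if (!is.null(seen_acc[[a]])) {
          logs[[length(logs) + 1L]] <<- tibble::tibble(
            level = "warning",
            message = paste0("duplicate accession: ", a))
        }
        seen_acc[[a]] <- TRUE
      }
      corpus <- sample_corpus(batch$records, batch$attributes)
      if (is.null(callback)) {
        batches[[length(batches) + 1L]] <<- corpus
      } else {
        callback(corpus)
      }
    }
  }

  repeat {
    lines <- readLines(con, n = 5000L, warn = FALSE)
    if (!length(lines)) break
    buffer <- paste0(buffer, paste(lines, collapse = "\n"), "\n")
    # normalise self-closing record elements so one close-tag form cuts
    # the stream (a tag straddling the chunk boundary stays in `buffer`
    # and is rewritten once its closing '>' arrives)
    buffer <- gsub("(<BioSample\\b[^>]*)/>", "\\1></BioSample>", buffer)
    # split on the record close tag: all but the last part hold one
    # complete element each (a sentinel preserves an empty tail part)
    parts <- strsplit(paste0(buffer, "\rEND"), "</BioSample>",
                      fixed = TRUE)[[1L]]
    k <- length(parts) - 1L
    if (k > 0L) {
      bodies <- parts[seq_len(k)]
      opens <- regexpr("<BioSample[ >]", bodies)
      if (any(opens < 0L)) {
        stop("malformed BioSample XML near character ",
             offset + nchar(bodies[[which(opens < 0L)[1L]]]), call. = FALSE)
      }
      pending <- c(pending,
                   paste0(substring(bodies, opens), "</BioSample>"))
      offset <- offset + sum(nchar(bodies)) + k * nchar("</BioSample>")
      buffer <- sub("\rEND$", "", parts[[k + 1L]])
      flush_pending()
    }
  }
  flush_pending(force = TRUE)

  # whatever remains must be document scaffolding (prolog, root element)
  leftover <- buffer
  if (total == 0L && length(batches) == 0L) {
    ok <- tryCatch({ xml2::read_xml(leftover); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      stop("malformed BioSample XML near byte ", offset, call. = FALSE)
    }
  } else if (grepl("<BioSample[ >]", leftover)) {
    stop("malformed BioSample XML: unterminated BioSample element after byte ",
         offset, call. = FALSE)
  }

  log_tbl <- if (length(logs)) dplyr::bind_rows(logs) else empty_parse_log()
  if (!is.null(callback)) {
    return(invisible(total))
  }
  records <- dplyr::bind_rows(c(list(empty_records()),
                                lapply(batches, `[[`, "records")))
  attributes <- dplyr::bind_rows(c(list(empty_attributes()),
                                   lapply(batches, `[[`, "attributes")))
  sample_corpus(records, attributes, parse_log = log_tbl)
}

parse_biosample_elements <- function(elements, offset) {
  doc <- tryCatch(
    xml2::read_xml(paste0("<BioSampleSet>", paste(elements, collapse = ""),
                          "</BioSampleSet>")),
    error = function(e) {
      stop("malformed BioSample XML near byte ", offset, ": ",
           conditionMessage(e), call. = FALSE)
    })
  nodes <- xml2::xml_find_all(doc, "/BioSampleSet/BioSample")
  log <- empty_parse_log()

  accession <- xml2::xml_attr(nodes, "accession")
  keep <- !is.na(accession) & accession != ""
  if (any(!keep)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      level = "error",
      message = sprintf("BioSample element %d has no accession; skipped",
                        which(!keep))))
  }
  nodes <- nodes[keep]
  accession <- accession[keep]

  # nodeset-vectorised field extraction (xml_find_first maps missing
  # elements to NA through xml_text/xml_attr)
  text1 <- function(xpath) {
    xml2::xml_text(xml2::xml_find_first(nodes, xpath))
  }
  org <- xml2::xml_find_first(nodes, "./Description/Organism")
  records <- tibble::tibble(
    record_id = xml2::xml_attr(nodes, "id"),
    accession = accession,
    repository = rep("NCBI", length(accession)),
    title = text1("./Description/Title"),
    publication_date = xml2::xml_attr(nodes, "publication_date"),
    last_update_date = xml2::xml_attr(nodes, "last_update"),
    submission_date = xml2::xml_attr(nodes, "submission_date"),
    organism_name = xml2::xml_attr(org, "taxonomy_name"),
    organism_taxon_id = xml2::xml_attr(org, "taxonomy_id"),
    owner = text1("./Owner/Name"),
    package = text1("./Package"))

  counts <- as.integer(xml2::xml_find_num(nodes,
                                          "count(./Attributes/Attribute)"))
  anodes <- xml2::xml_find_all(nodes, "./Attributes/Attribute")
  attributes <- tibble::tibble(
    accession = rep(accession, counts),
    position = sequence(counts),
    name = xml2::xml_attr(anodes, "attribute_name"),
    value = xml2::xml_text(anodes),
    term_source_ref = rep(NA_character_, length(anodes)),
    term_source_id = rep(NA_character_, length(anodes)))
  list(records = records, attributes = attributes, log = log)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a corpus as NCBI BioSample XML
#'
#' Serialises a corpus into a `BioSampleSet` document that
#' [read_biosample_xml()] parses back to field-identical records. Output
#' is deterministic: records in table order, attributes in `position`
#' order, and all special characters XML-escaped. An empty corpus yields
#' a well-formed empty `BioSampleSet`.
#'
#' @param corpus A [sample_corpus()]; every record needs an accession.
#' @param path Output file, or `NULL` to return the document as a string.
#' @return `path` invisibly, or the XML text when `path` is `NULL`.
#' @export
write_biosample_xml <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "sample_corpus"))
  recs <- corpus$records
  attrs <- corpus$attributes
  attrs <- attrs[order(match(attrs$accession, recs$accession), attrs$position), ]
  attr_by_acc <- split(attrs, factor(attrs$accession, levels = recs$accession))

  opt_attr <- function(name, value) {
    ifelse(is.na(value), "", sprintf(' %s="%s"', name, xml_escape(value)))
  }
  record_xml <- vapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    a <- attr_by_acc[[r$accession]]
    org <- if (!is.na(r$organism_name) || !is.na(r$organism_taxon_id)) {
      sprintf("<Organism%s%s/>",
              opt_attr("taxonomy_id", r$organism_taxon_id),
              opt_attr("taxonomy_name", r$organism_name))
    } else ""
    title <- if (!is.na(r$title)) {
      sprintf("<Title>%s</Title>", xml_escape(r$title))
    } else ""
    desc <- if (nzchar(title) || nzchar(org)) {
      sprintf("<Description>%s%s</Description>", title, org)
    } else ""
    owner <- if (!is.na(r$owner)) {
      sprintf("<Owner><Name>%s</Name></Owner>", xml_escape(r$owner))
    } else ""
    pkg <- if (!is.na(r$package)) {
      sprintf("<Package>%s</Package>", xml_escape(r$package))
    } else ""
    attr_xml <- if (!is.null(a) && nrow(a)) {
      sprintf("<Attributes>%s</Attributes>",
              paste0(sprintf('<Attribute attribute_name="%s">%s</Attribute>',
                             xml_escape(a$name), xml_escape(a$value)),
                     collapse = ""))
    } else ""
    sprintf("  <BioSample%s accession=\"%s\"%s%s%s>%s%s%s%s</BioSample>",
            opt_attr("id", r$record_id), xml_escape(r$accession),
            opt_attr("publication_date", r$publication_date),
            opt_attr("last_update", r$last_update_date),
            opt_attr("submission_date", r$submission_date),
            desc, owner, pkg, attr_xml)
  }, character(1))

  doc <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n<BioSampleSet>\n',
                paste0(record_xml, collapse = "\n"),
                if (nrow(recs)) "\n" else "", "</BioSampleSet>\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(path)
}
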