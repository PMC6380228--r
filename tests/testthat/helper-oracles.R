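# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the edit-distance oracle is the textbook
# dynamic-programming recurrence, and the timestamp oracle decides
# validity by set membership in an exhaustively enumerated language.

lev_oracle <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  m <- length(sa); n <- length(sb)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0:m
  d[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (sa[i] != sb[j]))
    }
  }
  d[m + 1L, n + 1L]
}

# --- timestamp grammar oracle -------------------------------------------
# component pools shared by the enumerator (valid members only) and the
# random string generator (valid and invalid members)

ts_pools <- local({
  months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  case_variants <- function(m) {
    ch <- strsplit(m, "")[[1]]
    masks <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
    apply(masks, 1L, function(up) {
      paste(ifelse(up, toupper(ch), tolower(ch)), collapse = "")
    })
  }
  list(
    months_ok = unique(unlist(lapply(months, case_variants))),
    months_bad = c("Janu", "Ja", "Marc", "Nvo", "Juny", "January", "013"),
    days_ok = c(as.character(1:31), sprintf("0%d", 1:9)),
    days_bad = c("0", "00", "32", "33", "311"),
    years_ok = c("1999", "2000", "0000", "2017"),
    years_bad = c("200", "20000", "15", "two thousand"),
    iso_mon_ok = sprintf("%02d", 1:12),
    iso_mon_bad = c("00", "13", "1", "9", "99"),
    iso_day_ok = sprintf("%02d", 1:31),
    iso_day_bad = c("00", "32", "1", "9", "99"),
    hh_ok = c("00", "09", "17", "23"),
    hh_bad = c("24", "25", "7"),
    mi_ok = c("00", "30", "59"),
    mi_bad = c("60", "5"),
    ss_ok = c("00", "20", "59"),
    ss_bad = c("61", "9"),
    delims = c("-", "/", " "),
    junk = c("no description", "unspecified", "missing", "", "late 2014")
  )
})

# every valid string composable from the pools, per the accepted shapes
ts_valid_language <- local({
  p <- ts_pools
  v1 <- as.vector(outer(as.vector(outer(p$days_ok, p$months_ok,
                                        paste, sep = "-")),
                        p$years_ok, paste, sep = "-"))
  v2 <- as.vector(outer(p$months_ok, p$years_ok, paste, sep = "-"))
  v3 <- p$years_ok
  v4 <- as.vector(outer(p$years_ok, p$iso_mon_ok, paste, sep = "-"))
  v5 <- as.vector(outer(v4, p$iso_day_ok, paste, sep = "-"))
  times <- as.vector(outer(as.vector(outer(p$hh_ok, p$mi_ok,
                                           paste, sep = ":")),
                           p$ss_ok, paste, sep = ":"))
  v6 <- as.vector(outer(v5, times, paste, sep = "T"))
  c(v1, v2, v3, v4, v5, v6)
})

ts_oracle <- function(x) trimws(x) %in% ts_valid_language

# random timestamp-shaped strings mixing valid and invalid components
ts_random_strings <- function(n) {
  p <- ts_pools
  pick <- function(ok, bad) {
    ifelse(runif(n) < 0.6, sample(ok, n, replace = TRUE),
           sample(bad, n, replace = TRUE))
  }
  day <- pick(p$days_ok, p$days_bad)
  mon <- pick(p$months_ok, p$months_bad)
  yr <- pick(p$years_ok, p$years_bad)
  im <- pick(p$iso_mon_ok, p$iso_mon_bad)
  id <- pick(p$iso_day_ok, p$iso_day_bad)
  hh <- pick(p$hh_ok, p$hh_bad)
  mi <- pick(p$mi_ok, p$mi_bad)
  ss <- pick(p$ss_ok, p$ss_bad)
  d1 <- sample(p$delims, n, replace = TRUE)
  d2 <- sample(p$delims, n, replace = TRUE)
  fam <- sample(7L, n, replace = TRUE)
  out <- character(n)
  out[fam == 1L] <- paste0(day, d1, mon, d2, yr)[fam == 1L]
  out[fam == 2L] <- paste0(mon, d1, yr)[fam == 2L]
  out[fam == 3L] <- yr[fam == 3L]
  out[fam == 4L] <- paste0(yr, "-", im)[fam == 4L]
  out[fam == 5L] <- paste0(yr, "-", im, "-", id)[fam == 5L]
  out[fam == 6L] <- paste0(yr, "-", im, "-", id, "T", hh, ":", mi, ":",
                           ss)[fam == 6L]
  out[fam == 7L] <- sample(p$junk, sum(fam == 7L), replace = TRUE)
  pad <- runif(n) < 0.1
  out[pad] <- paste0("  ", out[pad], " ")
  out
}

# --- tiny corpus fixtures ------------------------------------------------

ncbi_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_registry(metaqc_file("ncbi_profile.yaml"))
    reg
  }
})

ebi_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_registry(metaqc_file("ebi_profile.yaml"))
    reg
  }
})

local_resolver <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- term_resolver(metaqc_file("term_index.tsv"))
    res
  }
})

make_corpus <- function(attr_names, attr_values = attr_names,
                        accession = "SAMN00000001", package = NA_character_,
                        repository = "NCBI",
                        submission_date = "2015-06-01") {
  records <- tibble::tibble(
    record_id = accession, accession = accession, repository = repository,
    title = NA_character_, publication_date = NA_character_,
    last_update_date = NA_character_, submission_date = submission_date,
    organism_name = NA_character_, organism_taxon_id = NA_character_,
    owner = NA_character_, package = package)
  attributes <- tibble::tibble(
    accession = rep(accession[[1]], length(attr_names)),
    position = seq_along(attr_names),
    name = attr_names, value = attr_values,
    term_source_ref = NA_character_, term_source_id = NA_character_)
  sample_corpus(records, attributes)
}

sorted_attr_frame <- function(corpus) {
  a <- as.data.frame(corpus$attributes)
  a <- a[order(a$accession, a$name, a$value),
         c("accession", "name", "value", "term_source_ref", "term_source_id")]
  rownames(a) <- NULL
  a
}
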