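test_that("per-class summaries count attributes and records correctly", {
  results <- tibble::tibble(
    accession = c("A", "A", "B", "C", "C", "D"),
    attribute_name = "smoker",
    value = c("true", "false", "Yes", "true", "N", "true"),
    value_class = "boolean",
    status = c("well_specified", "well_specified", "invalid",
               "well_specified", "invalid", "well_specified"),
    reason = NA_character_)
  s <- summarize_by_type(results)
  expect_equal(s$attributes_total, 6L)
  expect_equal(s$attributes_well_specified, 4L)
  expect_equal(s$records_with_class, 4L)
  expect_equal(s$records_all_valid, 2L)     # A and D only
  expect_equal(s$percent_well_specified, 100 * 4 / 6)

  expect_equal(nrow(summarize_by_type(results[0, ])), 0L)

  # restricting to every accession equals the unfiltered summary
  expect_equal(summarize_by_type(results, accessions = c("A", "B", "C", "D")),
               s)
  # conservation: well + invalid = total
  expect_equal(s$attributes_well_specified + s$attributes_invalid,
               s$attributes_total)
})

test_that("package distribution defaults missing packages by repository", {
  ncbi <- make_corpus("strain", accession = "SAMN1")    # no package element
  d <- package_distribution(ncbi)
  expect_equal(d$package, "Generic")
  expect_equal(d$percent, 100)

  # EBI: the package reference is an attribute, absence means Unpackaged
  ebi <- sample_corpus(
    tibble::tibble(record_id = c("s1", "s2"), accession = c("s1", "s2"),
                   repository = "EBI", title = NA_character_,
                   publication_date = NA_character_,
                   last_update_date = NA_character_,
                   submission_date = NA_character_,
                   organism_name = NA_character_,
                   organism_taxon_id = NA_character_, owner = NA_character_,
                   package = NA_character_),
    tibble::tibble(accession = "s1", position = 1L, name = "package",
                   value = "Generic", term_source_ref = NA_character_,
                   term_source_id = NA_character_))
  d <- package_distribution(ebi)
  expect_equal(sum(d$n), 2L)
  expect_setequal(d$package, c("Generic", "Unpackaged"))
})

test_that("package distribution recovers the generator mix exactly", {
  cfg <- corpus_config(n_records = 200, seed = 5)
  g <- generate_corpus(cfg)
  d <- package_distribution(g$corpus)
  want <- table(g$ledger$records$package)
  expect_equal(sum(d$n), 200L)
  for (p in names(want)) {
    expect_equal(d$n[d$package == p], unname(want[p]), ignore_attr = TRUE)
  }
  # and the fractions are the configured ones, exactly apportioned
  counts <- metaqc:::exact_counts(cfg$package_mix, 200L)
  expect_equal(sort(as.integer(d$n)), sort(unname(counts[counts > 0])))
})

test_that("submissions per year bucket on the leading 4-digit field", {
  corpus <- make_corpus("strain", accession = "SAMN1",
                        submission_date = "2015-06-01")
  y <- submissions_per_year(corpus)
  expect_equal(y$year, "2015")
  bad <- make_corpus("strain", accession = "SAMN1",
                     submission_date = "June 2015")
  expect_equal(submissions_per_year(bad)$year, "unknown")

  g <- generate_corpus(corpus_config(n_records = 300, seed = 9))
  y <- submissions_per_year(g$corpus)
  want <- table(g$ledger$records$year)
  expect_equal(stats::setNames(y$n, y$year),
               stats::setNames(as.integer(want), names(want)))
  # split adds a Generic / non-Generic breakdown that sums to the total
  ysplit <- submissions_per_year(g$corpus, split = TRUE)
  expect_equal(sum(ysplit$n), 300L)
  expect_setequal(unique(ysplit$package_group), c("Generic", "non-Generic"))
})

test_that("the attribute-name census separates dictionary from custom names", {
  reg <- ncbi_registry()
  corpus <- make_corpus(c("sex", "age", "sex", "Altitude (m)", "weight_kg"),
                        c("male", "4", "female", "100", "70"))
  cen <- attribute_name_census(corpus, reg)
  expect_equal(cen$total_attributes, 5L)
  expect_equal(cen$unique_names, 4L)
  expect_equal(cen$dictionary_names_used, 2L)
  expect_equal(cen$custom_names, 2L)
  expect_equal(cen$attributes_using_custom_names, 2L)
  expect_equal(cen$records_touched_by_custom_names, 1L)
  expect_equal(cen$unique_names,
               cen$dictionary_names_used + cen$custom_names)
  expect_equal(cen$mean_attributes_per_record, 5)

  # corpus using only dictionary names has no custom names
  clean <- make_corpus(c("sex", "age"), c("male", "4"))
  expect_equal(attribute_name_census(clean, reg)$custom_names, 0L)
})

test_that("the census recovers planted custom variants exactly", {
  g <- generate_corpus(corpus_config(n_records = 150, seed = 3,
                                     custom_name_rate = 0.3))
  cen <- attribute_name_census(g$corpus, ncbi_registry())
  led <- g$ledger$attributes
  expect_equal(cen$total_attributes, nrow(led))
  expect_equal(cen$custom_names,
               length(unique(led$name[led$value_class == "custom"])))
  expect_equal(cen$attributes_using_custom_names,
               sum(led$value_class == "custom"))
  expect_equal(cen$records_touched_by_custom_names,
               length(unique(led$accession[led$value_class == "custom"])))
})

test_that("repository intersection matches the planted overlap exactly", {
  pair <- generate_corpus_pair(corpus_config(n_records = 80, seed = 1),
                               corpus_config(n_records = 60,
                                             repository = "EBI", seed = 2),
                               n_shared = 25L)
  ix <- intersect_repositories(pair$ncbi$corpus, pair$ebi$corpus)
  expect_equal(ix$n_shared, 25L)
  expect_equal(ix$shared_accessions, pair$shared_accessions)
  expect_gt(length(ix$shared_attribute_names), 0L)

  # disjoint and identical corpora as boundary cases
  a <- make_corpus("sex", accession = "SAMN1")
  b <- make_corpus("sex", accession = "SAME1", repository = "EBI")
  expect_equal(intersect_repositories(a, b)$n_shared, 0L)
  expect_equal(intersect_repositories(a, a)$n_shared, 1L)
})

test_that("term-source URI census classifies syntax and keeps variants distinct", {
  attrs <- tibble::tibble(
    accession = "s1", position = 1:4, name = "Organism",
    value = "Homo sapiens",
    term_source_ref = c("http://purl.obolibrary.org/obo/efo.owl",
                        "http://purl.obolibrary.org/obo/efo.owl/",
                        "http//example.org/ncbitaxon",
                        "http://purl.obolibrary.org/obo/efo.owl"),
    term_source_id = NA_character_)
  recs <- tibble::tibble(record_id = "s1", accession = "s1",
                         repository = "EBI", title = NA_character_,
                         publication_date = NA_character_,
                         last_update_date = NA_character_,
                         submission_date = NA_character_,
                         organism_name = NA_character_,
                         organism_taxon_id = NA_character_,
                         owner = NA_character_, package = NA_character_)
  corpus <- sample_corpus(recs, attrs)
  cen <- term_source_uri_census(corpus)
  expect_equal(nrow(cen), 3L)   # trailing slash is a distinct URI
  expect_equal(cen$class[cen$uri == "http//example.org/ncbitaxon"],
               "malformed")
  expect_equal(cen$n[cen$uri == "http://purl.obolibrary.org/obo/efo.owl"], 2L)

  expect_equal(nrow(term_source_uri_census(make_corpus("x"))), 0L)
})

test_that("concept groups count a record once however many members it uses", {
  groups <- tibble::tibble(
    concept = c("Age", "Age", "Weight"),
    attribute_name = c("age", "age_years", "weight_kg"))
  corpus <- make_corpus(c("age", "age_years", "depth"), c("4", "4", "2m"))
  out <- concept_record_counts(corpus, groups)
  expect_equal(out$n_records[out$concept == "Age"], 1L)
  expect_equal(out$n_records[out$concept == "Weight"], 0L)

  overlapping <- tibble::tibble(concept = c("A", "B"),
                                attribute_name = c("age", "age"))
  expect_warning(concept_record_counts(corpus, overlapping), "more than one")
})

test_that("name ranking reports both record and occurrence counts", {
  recs <- dplyr::bind_rows(lapply(c("r1", "r2", "r3"), function(a)
    make_corpus(c("age", "age", "sex")[seq_len(ifelse(a == "r1", 3, 1))],
                accession = a)$records))
  attrs <- dplyr::bind_rows(
    tibble::tibble(accession = "r1", position = 1:3,
                   name = c("age", "age", "sex"), value = "x",
                   term_source_ref = NA_character_,
                   term_source_id = NA_character_),
    tibble::tibble(accession = c("r2", "r3"), position = 1L,
                   name = "age", value = "x",
                   term_source_ref = NA_character_,
                   term_source_id = NA_character_))
  corpus <- sample_corpus(recs, attrs)
  r <- rank_names_by_use(corpus)
  expect_equal(r$name[1], "age")
  expect_equal(r$n_records[r$name == "age"], 3L)
  expect_equal(r$n_occurrences[r$name == "age"], 4L)
  expect_equal(r$n_records[r$name == "sex"], 1L)

  expect_equal(nrow(rank_names_by_use(make_corpus(character(0)))), 0L)
})

test_that("top-name categorisation joins the fixture and flags unmapped names", {
  corpus <- make_corpus(c("sex", "zzz_unheard_of"), c("male", "1"))
  out <- categorize_top_names(corpus, n = 10L)
  expect_equal(out$category[out$name == "sex"], "Biomedical characteristic")
  expect_equal(out$category[out$name == "zzz_unheard_of"], "unmapped")
})
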