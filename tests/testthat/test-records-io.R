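test_that("a BioSample element parses into one record with its attributes", {
  xml <- '<?xml version="1.0"?>
<BioSampleSet>
  <BioSample id="101" accession="SAMN01234567" publication_date="2016-01-05"
             last_update="2016-02-01" submission_date="2015-12-31">
    <Description>
      <Title>Liver sample</Title>
      <Organism taxonomy_id="9606" taxonomy_name="Homo sapiens"/>
    </Description>
    <Owner><Name>Hospital Biobank</Name></Owner>
    <Package>Human.1.0</Package>
    <Attributes>
      <Attribute attribute_name="age">34</Attribute>
      <Attribute attribute_name="sex">female</Attribute>
      <Attribute attribute_name="tissue">liver</Attribute>
    </Attributes>
  </BioSample>
</BioSampleSet>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  corpus <- read_biosample_xml(f)
  expect_equal(n_records(corpus), 1L)
  rec <- corpus$records
  expect_equal(rec$accession, "SAMN01234567")
  expect_equal(rec$repository, "NCBI")
  expect_equal(rec$package, "Human.1.0")
  expect_equal(rec$organism_name, "Homo sapiens")
  expect_equal(rec$organism_taxon_id, "9606")
  expect_equal(rec$submission_date, "2015-12-31")
  expect_equal(corpus$attributes$name, c("age", "sex", "tissue"))
  expect_equal(corpus$attributes$value, c("34", "female", "liver"))
  expect_equal(corpus$attributes$position, 1:3)
})

test_that("an empty BioSampleSet parses to an empty corpus", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<BioSampleSet></BioSampleSet>", f)
  corpus <- read_biosample_xml(f)
  expect_equal(n_records(corpus), 0L)
  expect_equal(nrow(corpus$attributes), 0L)
})

test_that("missing package or accession are handled per record", {
  xml <- paste0(
    "<BioSampleSet>",
    '<BioSample accession="SAMN1"><Attributes>',
    '<Attribute attribute_name="strain">K-12</Attribute>',
    "</Attributes></BioSample>",
    "<BioSample><Attributes/></BioSample>",   # no accession: logged, skipped
    '<BioSample accession="SAMN2"/>',
    "</BioSampleSet>")
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  corpus <- read_biosample_xml(f)
  expect_equal(corpus$records$accession, c("SAMN1", "SAMN2"))
  expect_true(all(is.na(corpus$records$package)))
  expect_match(parse_log(corpus)$message, "no accession", all = FALSE)
})

test_that("malformed XML raises a parse error naming a position", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<BioSampleSet><BioSample accession="SAMN1">', f)
  expect_error(read_biosample_xml(f), "malformed")
  writeLines("this is not xml at all", f)
  expect_error(read_biosample_xml(f), "malformed")
})

test_that("duplicate accessions are surfaced, not dropped", {
  xml <- paste0("<BioSampleSet>",
                '<BioSample accession="SAMN1"/>',
                '<BioSample accession="SAMN1"/>',
                "</BioSampleSet>")
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  corpus <- read_biosample_xml(f)
  expect_equal(n_records(corpus), 2L)
  expect_equal(duplicated_accessions(corpus), "SAMN1")
  expect_match(parse_log(corpus)$message, "duplicate accession", all = FALSE)
})

test_that("NCBI round trip reproduces generated corpora field by field", {
  for (seed in c(2, 17)) {
    g <- generate_corpus(corpus_config(n_records = 60, seed = seed))
    f <- withr::local_tempfile(fileext = ".xml")
    write_biosample_xml(g$corpus, f)
    back <- read_biosample_xml(f)
    expect_equal(as.data.frame(back$records),
                 as.data.frame(g$corpus$records))
    expect_equal(as.data.frame(back$attributes),
                 as.data.frame(g$corpus$attributes))
  }
})

test_that("XML special characters survive the round trip", {
  corpus <- make_corpus(c("note <odd>", "a&b"), c("x < y & z", "\"quoted\""))
  f <- withr::local_tempfile(fileext = ".xml")
  write_biosample_xml(corpus, f)
  back <- read_biosample_xml(f)
  expect_equal(as.data.frame(back$attributes),
               as.data.frame(corpus$attributes))
})

test_that("streaming callback sees every record without accumulating", {
  g <- generate_corpus(corpus_config(n_records = 120, seed = 4))
  f <- withr::local_tempfile(fileext = ".xml")
  write_biosample_xml(g$corpus, f)
  seen <- 0L
  total <- read_biosample_xml(f, callback = function(batch) {
    seen <<- seen + n_records(batch)
  }, chunk_records = 25L)
  expect_equal(seen, 120L)
  expect_equal(total, 120L)
})

test_that("SampleTab SCD parsing attaches term-source columns to the preceding attribute", {
  tab <- paste(
    "[MSI]",
    "Submission Title\tExample",
    "",
    "[SCD]",
    "Sample Name\tOrganism\tTerm Source REF\tTerm Source ID\tSex",
    "sample-1\tHomo sapiens\tNCBI Taxonomy\t9606\tfemale",
    sep = "\n")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(tab, f)
  corpus <- read_sampletab(f)
  expect_equal(n_records(corpus), 1L)
  expect_equal(corpus$records$repository, "EBI")
  expect_equal(corpus$records$organism_name, "Homo sapiens")
  org <- corpus$attributes[corpus$attributes$name == "Organism", ]
  expect_equal(org$term_source_ref, "NCBI Taxonomy")
  expect_equal(org$term_source_id, "9606")
  sex <- corpus$attributes[corpus$attributes$name == "Sex", ]
  expect_true(is.na(sex$term_source_ref))
  expect_match(parse_log(corpus)$message, "MSI section skipped", all = FALSE)
})

test_that("an MSI-only file yields an empty corpus with a warning log", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[MSI]", "Submission Title\tExample"), f)
  corpus <- read_sampletab(f)
  expect_equal(n_records(corpus), 0L)
  expect_match(parse_log(corpus)$message, "no SCD section", all = FALSE)
})

test_that("ragged SCD rows are skipped with a row-level error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[SCD]",
               "Sample Name\tOrganism\tSex",
               "s1\tHomo sapiens\tmale",
               "s2\tMus musculus",          # ragged: one field short
               "s3\tDanio rerio\tfemale"), f)
  corpus <- read_sampletab(f)
  expect_equal(corpus$records$accession, c("s1", "s3"))
  expect_match(parse_log(corpus)$message, "expected 3", all = FALSE)
})

test_that("rows sharing a Sample Name become records with flagged duplicates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[SCD]",
               "Sample Name\tOrganism",
               "s1\tHomo sapiens",
               "s1\tMus musculus"), f)
  corpus <- read_sampletab(f)
  expect_equal(n_records(corpus), 2L)
  expect_equal(duplicated_accessions(corpus), "s1")
})

test_that("SampleTab round trip preserves records and attribute multisets, and serialisation is a fixed point", {
  g <- generate_corpus(corpus_config(n_records = 50, repository = "EBI",
                                     seed = 8))
  f <- withr::local_tempfile(fileext = ".txt")
  write_sampletab(g$corpus, f)
  back <- read_sampletab(f)
  expect_equal(as.data.frame(back$records), as.data.frame(g$corpus$records))
  expect_equal(sorted_attr_frame(back), sorted_attr_frame(g$corpus))

  # the table imposes one shared column order; after one pass through it,
  # serialisation is byte-stable
  s2 <- write_sampletab(back)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(s2, f2, sep = "")
  s3 <- write_sampletab(read_sampletab(f2))
  expect_identical(s2, s3)
})

test_that("duplicate attribute names within a record survive the SampleTab round trip", {
  corpus <- make_corpus(c("synonym", "synonym", "depth"),
                        c("liver", "hepatic", "10m"),
                        accession = "SAME1", repository = "EBI",
                        submission_date = NA_character_)
  f <- withr::local_tempfile(fileext = ".txt")
  write_sampletab(corpus, f)
  back <- read_sampletab(f)
  expect_equal(back$attributes$name, c("synonym", "synonym", "depth"))
  expect_equal(back$attributes$value, c("liver", "hepatic", "10m"))
})

test_that("tab-containing values are refused rather than silently corrupted", {
  corpus <- make_corpus("note", "has\ttab", accession = "SAME1",
                        repository = "EBI")
  expect_error(write_sampletab(corpus), "tab")
})

test_that("record and attribute counts are conserved through parsing", {
  g <- generate_corpus(corpus_config(n_records = 80, seed = 21))
  f <- withr::local_tempfile(fileext = ".xml")
  write_biosample_xml(g$corpus, f)
  back <- read_biosample_xml(f)
  expect_equal(n_records(back), 80L)
  expect_equal(nrow(back$attributes), nrow(g$corpus$attributes))
})
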