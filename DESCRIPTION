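Package: metaqc
Title: Quality Assessment of Biological Sample Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the quality of sample metadata stored in
    biosample repositories. Parses NCBI BioSample XML and EBI BioSamples
    SampleTab records into a common model, validates attribute values against
    a declarative registry of typed attribute specifications (boolean,
    integer, timestamp, value-set, and ontology-term attributes), aggregates
    per-repository quality reports, and clusters attribute names by
    Levenshtein edit distance with affinity propagation to surface redundant
    field-name variants. Includes a synthetic corpus generator with an exact
    ground-truth ledger so the entire pipeline can be exercised without
    repository downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    xml2,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
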