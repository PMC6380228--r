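---
title: "Auditing biosample metadata quality with metaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing biosample metadata quality with metaqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaqc)
```

## The problem

Public biosample repositories — NCBI BioSample and EBI BioSamples — store
millions of metadata records describing the biological materials behind
deposited experiments. Each record is essentially a list of *attributes*:
name–value pairs such as `sex = female` or `collection_date = 20-Nov-2000`.
Both repositories document what well-formed values look like for a subset of
attribute names: some must be booleans, some integers, some dates, some must
come from a closed value set, and some must be terms from a designated
ontology. In practice submitters routinely deviate from those expectations,
and they also invent their own attribute names (`Altitude (m)` instead of the
dictionary's `altitude`; `weight_kg`, `weight (kg)`, `Weight..kg.` for the
same measurement), which degrades the findability and reusability of the
underlying data.

metaqc packages a complete audit pipeline for this situation:

1. **Parsing** — NCBI BioSample XML dumps and EBI SampleTab files stream into
   one tidy corpus model (`sample_corpus`).
2. **Validation** — every attribute occurrence is checked against a
   declarative registry of typed attribute specifications.
3. **Reporting** — per-class quality tables, package and submission-year
   distributions, attribute-name censuses, cross-repository intersections,
   term-source URI audits, and concept-level record counts.
4. **Name clustering** — Levenshtein-distance affinity propagation groups
   redundant attribute-name variants around exemplar names.
5. **Synthetic corpora** — a generator with an exact ground-truth ledger, so
   the whole pipeline is testable end to end without repository downloads.

## The record model

A corpus is two tables. `records` has one row per sample record: accession,
repository, raw submission/publication/update dates, organism, owner, and
package. `attributes` has one row per attribute *occurrence*: accession,
position within the record, name, value, and (for the SampleTab dialect) the
`Term Source REF`/`Term Source ID` fields that tie a value to an ontology.

Two choices here shape everything downstream:

* **Verbatim storage.** Names and values are never trimmed, case-folded or
  otherwise normalised at parse time. The censuses count *syntactically
  unique* names — `sex`, `Sex` and `sex ` (trailing space) are three
  different strings until a report decides otherwise — so normalisation is
  applied per analysis (surrounding-whitespace trim for name identity;
  nothing else).
* **Raw dates.** Submission dates may themselves be malformed, so they stay
  text; `submissions_per_year()` extracts a leading 4-digit year and buckets
  everything else as `"unknown"`.

Missing packages are represented as `NA` at parse time and mapped to
`Generic` (NCBI) or `Unpackaged` (EBI) only when reporting, since the absence
of a package element and an explicit Generic label mean the same thing for
quality purposes. For EBI records the package reference is an ordinary
attribute named `package`, mirroring how such references appear there.

The NCBI reader cuts record elements out of the byte stream and parses them
in batches, so memory tracks the batch size rather than the dump size; a
`callback` argument processes batches without accumulating them. The
SampleTab reader consumes only the SCD section (the MSI section describes
the submission, not the samples, and is skipped with a log line). Parsing
never dies on a bad record: records without accessions, ragged rows, and
duplicated accessions are logged in `parse_log()` and parsing continues,
with de-duplication policy left to the caller.

One representational limit is worth knowing: SampleTab's SCD is a single
table with one shared column order, so per-record attribute order is
canonicalised to that column order on a round trip. Serialising, parsing and
re-serialising is byte-stable, and record fields and attribute multisets are
preserved exactly; only the original per-record interleaving is not
representable. The SCD also carries no dates, owner or taxon ids.

## Attribute specifications and validation

The registry (`load_registry()`) is data, not code: a YAML profile listing
attribute specs (`name`, `class`, optional `harmonized_name`, a `value_set`
or `ontology` binding), the value sets themselves, and package definitions
with required/optional attribute names. The shipped NCBI profile has 452
dictionary names — 4 boolean, 4 integer, 11 timestamp, 32 value-set, 9
ontology-term, and 392 without a machine-testable grammar (free text,
unit-bearing measurements, identifiers), marked `unchecked`. The repository
documentation names only a few members of each validated group; the fixture
completes the memberships with names and value sets modelled on the
BioSample/MIxS attribute documentation and can be edited without touching
code. The EBI profile holds the three named attributes: `Organism`
(ontology-term, NCBI Taxonomy), `Material` (ontology-term, any indexed
ontology), and `Sex`, validated against the NCBI sex value set so results
are comparable across repositories.

Dictionary-name matching trims surrounding whitespace and is otherwise
case-sensitive and exact (canonical or harmonized spelling). Case-sensitivity
is deliberate: the name census treats case variants as distinct custom
names, and a case-insensitive dictionary would silently reclassify them.

Each checked class has one validator; all of them trim surrounding
whitespace first, and a value that is empty or all whitespace is *invalid*,
not untested (an attribute that is present but blank is a filled-in field
with a bad value):

* **boolean** — `true`/`false` in any capitalisation; `f`, `yes`, `0`,
  `never smoker` and friends are invalid.
* **integer** — an optional single sign followed by decimal digits. Floats,
  thousands separators and scientific notation are rejected: "parses as an
  integer" is read strictly.
* **timestamp** — one of `D-Mmm-YYYY`, `Mmm-YYYY`, `YYYY` (1–2 digit day
  1–31, English three-letter month, case-insensitive) or ISO 8601 `YYYY-mm`,
  `YYYY-mm-dd`, `YYYY-mm-ddThh:mm:ss` with zero-padded components. These are
  *format* checks only: no calendar arithmetic (31-Feb passes), no timezone
  designators, no semantic bound on the year. The accepted shapes are
  pattern-level by design — the audit asks whether a value is parseable, not
  whether the experiment happened on a real date.
* **value set** — equality against a closed set, ignoring letter case and
  nothing else; internal characters must match exactly, so `mal e` and
  `femLE` fail.
* **ontology term** — exact match against the designated ontology's terms:
  preferred label, any synonym, or the term identifier, case-insensitive
  after trimming. No fuzzy matching: `lung_squamous_carcinoma` does not
  match a label that differs only by underscores, which is precisely the
  kind of near-miss the audit is meant to expose.

Term lookup goes through a pluggable resolver. The default is a local
tab-delimited index (`term_resolver()`); anything honouring the same
contract — including a client for a remote exact-search service — can be
substituted. A resolver failure yields status `untested` with reason
`resolver_error`, never a silent `invalid`: network trouble must not look
like bad metadata. Attributes without a spec (`no_spec`) or with an
`unchecked` spec are likewise `untested`, so every occurrence gets exactly
one of three statuses, with a reason code for machine consumption.

## Reports

`summarize_by_type()` aggregates verdicts per value class: how many records
carry the class, how many of those are clean, attribute totals, and the
percentage well-specified. Percentages are stored exact; round for display.
An `accessions` filter supports the packaged-records and
shared-with-the-other-repository sub-analyses. `attribute_name_census()`
separates dictionary from custom names; `intersect_repositories()` compares
corpora by exact accession equality; `term_source_uri_census()` classifies
the distinct ontology URIs syntactically (a URI without a colon after its
scheme is malformed; variants differing by a trailing slash stay distinct);
`concept_record_counts()` counts records touched by curated concept groups,
each record once per concept regardless of how many member names it uses.
The concept groups and top-name categories are editable TSV fixtures —
curation artefacts, not algorithm output.

## Name clustering

Similarity between attribute names is the negated Levenshtein distance
(`utils::adist`; unit-cost insertions, deletions, substitutions). Clustering
uses affinity propagation, implemented in the package: exemplar-based
message passing that neither fixes the number of clusters upfront nor
invents centroids outside the data — both properties the harmonisation task
needs, since the number of name variants per concept is unknown and the
exemplar must be a real attribute name.

Defaults: shared preference = median of the *off-diagonal* similarities,
damping 0.5, at most 1000 iterations, convergence declared after 15
iterations of a stable exemplar set, and a seeded jitter of about 1e-8 of
the similarity scale to break ties. Every run with the same inputs,
parameters and seed gives the identical partition, and the parameters are
recorded in the result. Exact ties are real in this problem — a point whose
best similarity to any exemplar equals the preference is indifferent — and
tie-break noise then decides; the documented default seed resolves the
`Submitted by`/`Submitter`/`Submitters` example into one cluster. Names that
are identical at distance 0 (case collisions under `casefold = TRUE`) are
merged before message passing, so distance-0 pairs can never split.

The similarity matrix is dense, so clustering all ~30k names of a full
repository snapshot needs ~1e9 entries; at that scale, pre-filter names by
use frequency (`rank_names_by_use()`) or cluster per repository. The package
clusters hundreds of names in seconds.

## The synthetic generator

`generate_corpus()` builds corpora whose statistical structure is known
exactly. Every fraction in the configuration — package mix, submission-year
histogram, per-class validity, custom-name rate — is realised by
largest-remainder rounding to integer counts, never by independent draws.
The returned ledger covers every generated attribute occurrence with its
intended class, validity and (for fabricated name variants) source name, so
report recovery is tested as *equality*, not statistically.

Defaults are the repository conditions the reports are designed around: a
package mix dominated by Generic (85%), submissions concentrated in recent
years, per-class validity of 0.27 (boolean), 0.74 (integer), 0.74
(timestamp), 0.92 (value set) and 0.32 (ontology term), twelve attributes
per record (five typed, seven free-form), and 15% of all attribute pairs
using submitter-invented custom names fabricated by `perturb_name()`
(seeded single-character edits plus decoration affixes like `_kg`).
Invalid values come from class-aware pools of realistic mistakes — boolean
synonyms (`Yes`, `N`, `never smoker`), malformed dates (`1800/2014`,
`Jan-Feb 2009`, free text), value-set members corrupted by internal spaces,
doubling, drops or truncation with membership re-checked after corruption,
and ontology labels broken by underscores or trailing qualifiers with the
index re-checked — so a correct validator can never accept them.

What the generator does *not* emulate: real organism taxonomies, biologically
plausible value co-occurrence, free-text semantics, per-package attribute
profiles, or the long-tailed name distributions of real snapshots. Passing
the recovery tests therefore demonstrates that the pipeline's accounting is
exact under known structure — not that real repositories have any particular
quality level. Real-snapshot numbers come from running the same pipeline on
the actual dumps.

## Numerical and design choices

* Exact-count composition uses largest-remainder apportionment with ties
  broken by listed order; validity counts use `floor(f·n + 0.5)`.
* The timestamp grammar, boolean set, and value-set comparison are all
  verified against brute-force oracles in the test suite (an enumerated
  valid-language oracle for dates; a textbook DP recurrence for edit
  distance, exhaustively for all pairs of length ≤ 4 over a 3-letter
  alphabet plus randomised longer pairs and 10^4 metric triples).
* Test problem sizes: the end-to-end recovery corpus is 10,000 records
  (120,000 attributes); clustering sanity runs at up to 500 names; grammar
  oracle comparisons use 10^4 generated strings. These sizes exercise every
  code path at comfortable margins while keeping the suite quick.
* Degenerate inputs: empty corpora produce empty (zero-row) reports;
  `summarize_by_type()` omits percentage rows rather than dividing by zero;
  an affinity-propagation run that fails to converge returns the current
  solution flagged `converged = FALSE`; a single name is its own exemplar.

## Limitations

* Only the five computationally unambiguous attribute groups are validated;
  unit-bearing measurements, PubMed-ID attributes and free text are reported
  as `untested`, matching the audit's scope.
* Edit distance is blind to semantics: `mass` and `weight` will not
  co-cluster however the parameters are set. Concept groups bridging such
  synonyms are curated fixtures.
* The local term index ships as a small synthetic subset of real ontologies,
  sufficient for exact-match behaviour; auditing a real snapshot needs an
  index built from the full ontologies.
* URI auditing is syntactic only; whether a URI actually resolves is out of
  scope.
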