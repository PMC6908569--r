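---
title: "Design-driven FAIRification of omics results matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-driven FAIRification of omics results matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairomics)
```

## The problem

Supplementary tables in metabolomics papers are typically wide matrices:
one row per compound, one column per condition-and-statistic pair, with a
header like `R. chinensis 'Old Blush' sepals — average`. A human reads
that header effortlessly; a software agent cannot. Three distinct kinds of
information are packed into it — which treatment the column describes
(a tuple of factor levels: cultivar, flower part), which statistic it
reports (a sample mean, not a raw value), and implicitly, the design the
treatments were drawn from. `fairomics` recovers that structure
explicitly: the matrix becomes a three-dimensional *data cube* (molecular
entities × treatments × quantitation types), the design is inferred and
classified, free-text labels are anchored to ontology terms, and the
result is emitted as a validated Tabular Data Package and as an RDF graph
that answers design-level queries.

## The data cube model

A `data_cube` holds:

* **molecular entities** — one per row of the source matrix, with the
  verbatim label, a normalized label (case-folded, whitespace-collapsed,
  typographic characters mapped to ASCII, Greek letters transliterated),
  and, after annotation, a chemical-entity CURIE, IRI and InChI;
* **factors and levels** — the independent variables recovered from the
  headers, each an ordered set of categorical levels;
* **observed treatments** — the distinct level tuples seen across
  columns;
* **quantitation types** — the statistic each column reports, canonized
  to `sample_mean` / `standard_error_of_mean` / `other`;
* **measurements** — one record per (entity, treatment, qtype) cell,
  with value, unit, sample size and replicate semantics.

`check_cube()` verifies every structural invariant (reference integrity,
uniqueness keys, CURIE syntax, the rule that a sample mean must carry a
sample size) and reports violations rather than raising, so partially
broken cubes remain inspectable. Missing cells are retained as records
with a missing value, never dropped: the cube's shape stays auditable and
the matrix ↔ cube mapping is lossless.

## Header grammar as configuration

The original curation of such tables was manual. Here the decomposition
is driven by a `header_spec` document: ordered regular-expression rules
whose capture groups are assigned to factor slots or to the
quantitation-type slot, plus a synonym table mapping captured tokens to
canonical labels (`sepals` → `sepal`, `old blush` → `Old Blush`). Exactly
one rule may match a header; zero or several matches are reported as
unpacking findings (errors in strict mode, a collected report in lenient
mode). Headers are normalized before matching — whitespace collapsed,
typographic quotes and dashes mapped to ASCII — and matching is
case-insensitive by default, so ordinary spreadsheet noise does not
require new rules.

Two pieces of metadata cannot come from the matrix at all and enter
through the same configuration file: the **unit** (carried verbatim,
never interpreted) and the **sample size** behind each summary statistic,
together with its **replicate semantics**. The distinction matters
scientifically: when replicates are technical (one biomaterial assayed
repeatedly), the SEM estimates measurement variability only, and the
design report carries that caveat explicitly rather than letting the
reader assume biological variability.

## Design inference

With the factor level sets in hand, the theoretical treatment space is
their cartesian product (`cartesian_treatments()`, first factor varying
slowest). The observed treatments are compared against it and the design
is classified by a trichotomy: `single_factor` (one factor),
`full_factorial` (≥ 2 factors, every combination observed), or
`fractional_factorial` (≥ 2 factors, a strict non-empty subset observed).
Only crossed categorical factors are modelled; there is no notion of
blocking, nesting or covariates, and no attempt to classify balance —
group sizes are carried per treatment so unbalanced designs remain
expressible, but a single stated *n* is the common case.

In the exemplar structure the two factors have 6 and 3 levels, so 18
combinations are theoretically possible; 8 are observed, and the design
classifies as fractional factorial.

## Annotation

Term resolution is offline and exact: per-domain term maps (chemical,
taxon, anatomy, statistic) are local YAML dictionaries keyed by
normalized label, with a synonym table per map. There is deliberately no
fuzzy matching — imprecise free-text naming is the problem being
corrected, and silent approximate resolution would reintroduce it. A
label resolves, is ambiguous (the map lists candidates), or stays
unresolved; the three statuses partition the submitted labels and the
`annotation_report` accounts for every one. Which ontology applies to
which factor is itself explicit configuration (`routing`), since nothing
in a header says that a cultivar is a taxon. The resolver interface is
the term map; a live lookup client can be wrapped as one without touching
the rest of the pipeline.

## Serialization choices

The data package writer emits one denormalized `measurements` resource —
every tidy column present, factor levels repeated per row — because a
single self-contained CSV travels best; a normalized multi-resource
layout was considered and deliberately left out of scope. Determinism is
treated as a contract: fixed field order, numbers written as shortest
round-trip decimals (15 significant digits, `.` decimal mark), missing
cells as the empty string (the token list is declared in the
descriptor), LF line endings. The same cube always produces byte-identical
files, and `read_package(write_package(x))` equals `x` up to canonical
ordering. Column-level semantics (term IRIs) live in the table schema;
cell-level chemical identity lives in dedicated CURIE/InChI columns.

The RDF graph mints no blank nodes: every instance IRI is a deterministic
function of the study id and the node's identifying labels, so double
builds are statement-identical. Ontology accessions for the model's
concepts (sample mean, standard error of the mean, fractional factorial
design, ...) are configuration in the vocabulary map, not logic — the
defaults are OBO-style CURIEs chosen by the package and can be retargeted
wholesale. The two built-in queries — predictor variables with their
levels, and the sample size behind the mean — are implemented as graph
traversals whose answers are contractually equal to those computed from
the in-memory model; equivalent SPARQL text ships under
`inst/queries/` as documentation. N-Triples output is canonically sorted
for byte determinism; Turtle output is the readable form.

The ISA-Tab output is an investigation stub only: ontology-source,
investigation, study and study-assay sections plus one
`Comment[Tabular Data Package]` row per referenced package. Sample-level
study/assay tables are out of scope.

## Cross-study comparison

Two cubes are joined on the strongest identifier available per entity:
CURIE first, then InChI, then normalized label, with the key type
recorded per entity so low-confidence (label-keyed) joins are auditable.
The comparison yields membership sets, a membership matrix and the three
disjoint region counts (UpSet convention), which satisfy
inclusion–exclusion by construction. Overlap significance testing and
quantitative concordance are intentionally absent.

## What the synthetic generator emulates

`generate_study()` reproduces the *structure* of the exemplar
supplementary table: 61 compounds; factors cultivar (6 levels, one
reference cultivar) and organism part (sepal, petal, stamen); the
8-of-18 observed layout built as all cultivars at sepal plus the
reference cultivar at all parts (a derived-consistent construction — the
union 6 + 3 − 1 = 8 — not a claim about any real study's exact column
set); sample mean and SEM columns over *n* = 3 technical replicates;
composed headers with an em-dash statistic separator. Values are
log-normal (location log 100, per-entity spread 0.8, per-treatment effect
scale 0.3) because metabolite abundances are positive and right-skewed;
the parameters are arbitrary but fixed. SEMs are generated as
per-treatment dispersion / √n so the mean–SEM relationship is internally
consistent, and all values are rounded to 6 significant digits at
generation so files round-trip bit-exactly. Matched term maps and the
header spec are written alongside, and a ground-truth object (cube,
design, dispersions) lets every downstream module be verified without
re-deriving anything from files.

What the generator does **not** emulate: real concentration values, real
header irregularities beyond the declared perturbation classes
(`generate_messy_variant()` injects case/quote/whitespace noise,
undeclared tokens, ragged rows, non-numeric cells), partial chemical
coverage of real vocabularies (coverage is complete unless
`n_unresolved` is set), or correlated missingness. Passing tests
therefore demonstrate that the machinery is lossless and self-consistent
on regular matrices of this shape — not that any particular real
supplementary file will ingest without a tailored header spec.

## Numerical and degenerate-input choices

* Value parsing honours a declared decimal mark (`.` default; comma
  input must be declared, never guessed) and a configurable
  missing-token list (`""`, `nd`, `n.d.`, `tr`, `NA`).
* Cube equality uses an absolute tolerance of 1e−9 on measurement
  values; everything else is compared exactly.
* An empty cube is valid: it packages with a complete schema and zero
  rows, serializes to an empty N-Triples file, and has shape (0, 0, 0).
* A cube observing no treatments has no defined classification and is
  rejected with an explicit error, as are observed treatments outside
  the theoretical space (possible only for hand-built cubes).
* Ties in the overlap region table break lexicographically on the
  region label, after the descending count sort.

## Problem sizes used in the test suite

The suite exercises the exemplar at full size (61 × 8 × 2 = 976 cells),
package round trips over 100 randomized small cubes (≤ 4 entities,
≤ 3 factors), graph/model query equivalence over 50 randomized designs,
and an end-to-end design-recovery sweep over 1–4 factors with 2–6 levels
in full and fractional layouts. These sizes give complete structural
coverage of the model space while keeping the whole suite fast on one
CPU.

## Known limitations

* One matrix, one cube: multi-sheet or multi-table inputs must be
  ingested separately and compared afterwards.
* No xlsx or PDF extraction; inputs are delimited text.
* The RDF model is OBO-anchored, not W3C RDF Data Cube (`qb:`)
  conformant; `qb:` alignment would be future work.
* Ontology accessions in the shipped defaults are placeholders chosen by
  the package; production use should pin accessions from the ontology
  releases in force.
* The comparison module handles exactly two studies.
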