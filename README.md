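# fairomics

Experiment-design-driven FAIRification of omics results matrices.

## The problem

A typical metabolomics supplementary table is a wide matrix: one row per
compound and one column per condition-and-statistic pair, with composed
headers such as `R. chinensis 'Old Blush' sepals — average`. Everything a
machine would need is hidden in those headers: the column is really a cell
of a three-dimensional **data cube**

> molecular entities × treatments × quantitation types,

where each treatment is a tuple of factor levels drawn from the study's
design, and each quantitation type is a statistic (a sample mean or a
standard error of the mean, each computed over *n* replicates). With
factors *F₁, …, F_k* carrying *ℓ₁, …, ℓ_k* categorical levels, the
theoretical treatment space is the cartesian product (|Π| = ∏ᵢ ℓᵢ); the
design is *full factorial* when every combination is observed,
*fractional factorial* when only a strict subset is. In the exemplar
structure the package emulates, 6 cultivars × 3 flower parts give 18
theoretical treatments of which 8 are observed — a fractional factorial.

`fairomics` makes all of that explicit and machine-actionable. It is
aimed at data curators and computational biologists retro-fitting FAIR
semantics onto published results tables, and at experimentalists who want
to publish matrices that software agents can query.

The pipeline:

1. **ingest** — read the wide matrix and *unpack* each composed header
   into factor levels plus a quantitation type, driven by a declarative
   header grammar (`header_spec`), producing a validated `data_cube`;
2. **design** — enumerate the theoretical treatment space, classify the
   design, attach group sizes and replicate semantics;
3. **annotate** — resolve compound / cultivar / anatomy / statistic
   labels against offline ontology term maps (ChEBI-, NCBITaxon-, PO-,
   STATO-style identifiers plus InChI), with an exact-match-only
   contract;
4. **package** — emit a Frictionless-style Tabular Data Package
   (`datapackage.json` + CSV, byte-deterministic) and an ISA-Tab
   investigation stub;
5. **linked data** — build a deterministic RDF graph, serialize to
   N-Triples/Turtle, and answer design-level queries ("retrieve the
   predictor variables and their levels", "what sample size is behind
   the mean?");
6. **compare** — identifier-keyed metabolite overlap between two
   FAIRified studies, with Venn/UpSet-ready disjoint region counts.

A deterministic synthetic-study generator (`generate_study()`,
`generate_pair()`, `generate_messy_variant()`) reproduces the exemplar
structure — 61 metabolites, the 8-of-18 layout, mean + SEM over n = 3
technical replicates — together with matched term maps and a ground-truth
object, so the whole pipeline is testable end to end without any network
access or real data.

## Worked example

```r
library(fairomics)

dir <- file.path(tempdir(), "exemplar")
truth <- generate_study(fixture_params(), dir)   # matrix + configs + truth

m    <- read_matrix(file.path(dir, "matrix.csv"))
cube <- unpack_headers(m, read_header_spec(file.path(dir, "header_spec.yaml")),
                       study_id = "rose-exemplar")
maps <- lapply(Sys.glob(file.path(dir, "term-map-*.yaml")), read_term_map)
ann  <- annotate_cube(cube, maps,
                      routing = c("rose cultivar" = "taxon",
                                  "organism part" = "anatomy"))
ann$cube
#> <data_cube> study 'rose-exemplar': 61 entities x 8 treatments x 2 quantitation types
#>   factors: rose cultivar (6 levels), organism part (3 levels)
#>   measurements: 976
ann$report
#> <annotation_report>
#>   anatomy   3 labels: 3 resolved, 0 ambiguous, 0 unresolved
#>   chemical  61 labels: 61 resolved, 0 ambiguous, 0 unresolved
#>   statistic 2 labels: 2 resolved, 0 ambiguous, 0 unresolved
#>   taxon     6 labels: 6 resolved, 0 ambiguous, 0 unresolved

infer_design(ann$cube)
#> Design: fractional_factorial (8 of 18 theoretical treatments observed)
#> Independent variables: 2
#>   - rose cultivar: 6 levels (Old Blush, Damask Pearl, Crimson Rambler, Tea Noisette, Maiden Blush, Autumn Damask)
#>   - organism part: 3 levels (sepal, petal, stamen)
#> Group size: n = 3 per treatment
#> Replicate semantics: technical
#> Replicates are technical: the standard error estimates measurement
#> variability, not biological variability.
```

Reading: the 61 rows and 16 data columns collapse to a cube of 976
measurement cells; the two recovered independent variables span 18
theoretical treatments of which 8 were observed, so the design is a
fractional factorial; every free-text label found an ontology term; and
because the three replicates behind each mean are technical, the SEM
quantifies the platform, not the biology.

From here, `write_package(ann$cube, out_dir)` emits the validated data
package, `build_graph()` + `serialize_graph()` the RDF, and
`query_predictors()` / `query_sample_size()` answer the design queries
from the graph alone. `compare_studies()` on two cubes returns the
shared/exclusive metabolite regions.

A thin command-line front-end wraps the same functions
(`inst/cli/fairomics.R`): subcommands `fairify`, `validate`, `query`,
`compare`, `make-fixture`, `inspect-design`; exit codes 0 (success),
1 (validation failure), 2 (configuration error).

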