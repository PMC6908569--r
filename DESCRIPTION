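Package: fairomics
Title: Experiment-Design-Driven FAIRification of Omics Data Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the data-cube semantics of wide-format omics results
    matrices (molecular entities x treatments x quantitation types), infers
    the underlying factorial design from composed column headers, annotates
    labels with ontology terms from offline term maps, and emits validated
    Tabular Data Packages, an RDF graph with built-in design queries, an
    ISA-Tab investigation stub, and cross-study metabolite overlap tables.
    Includes a deterministic synthetic-study generator emulating a targeted
    metabolite profiling matrix (61 compounds, cultivar x organism-part
    fractional factorial design) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
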