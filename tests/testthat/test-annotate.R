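stat_map <- function() {
  term_map("statistic",
           entries = list(
             "average" = list(curie = "STATO:0000401", label = "sample mean"),
             "standard error" = list(curie = "STATO:0000037",
                                     label = "standard error of the mean")),
           synonyms = c(mean = "average", sem = "standard error"))
}

test_that("normalize_label trims, folds case, and transliterates", {
  expect_equal(normalize_label("  Geraniol "), "geraniol")
  expect_equal(normalize_label("β-ionone"), "beta-ionone")
  expect_equal(normalize_label("‘Old  Blush’"), "'old blush'")
  # idempotence on already-normal labels and after one pass
  labels <- c("geraniol", "  Geraniol ", "α-Pinene", "A—B")
  once <- normalize_label(labels)
  expect_equal(normalize_label(once), once)
})

test_that("resolve_label finds statistics by label and synonym, never guesses", {
  m <- stat_map()
  r <- resolve_label("average", m)
  expect_equal(r$status, "resolved")
  expect_equal(r$term$label, "sample mean")
  expect_equal(r$term$curie, "STATO:0000401")
  r2 <- resolve_label("Standard Error", m)
  expect_equal(r2$term$label, "standard error of the mean")
  r3 <- resolve_label("sem", m)   # via synonym table
  expect_equal(r3$term$curie, "STATO:0000037")
  r4 <- resolve_label("unknown-compound-x", m)
  expect_equal(r4$status, "unresolved")
  expect_null(r4$term)
})

test_that("ambiguous aliases are rejected at map construction", {
  expect_error(
    term_map("chemical",
             entries = list(a = list(curie = "CHEBI:1"),
                            b = list(curie = "CHEBI:2")),
             synonyms = c(x = "a", X = "b")),
    "ambiguous")
})

test_that("entries with candidate lists resolve as ambiguous", {
  m <- term_map("chemical", entries = list(
    ionone = list(candidates = list(list(curie = "CHEBI:1"),
                                    list(curie = "CHEBI:2")))))
  r <- resolve_label("Ionone", m)
  expect_equal(r$status, "ambiguous")
  expect_length(r$candidates, 2L)
})

test_that("term maps survive a YAML round trip", {
  m <- stat_map()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_term_map(m, p)
  m2 <- read_term_map(p)
  expect_equal(m2$domain, "statistic")
  expect_equal(resolve_label("mean", m2)$term$curie, "STATO:0000401")
})

test_that("annotating the exemplar fixture resolves every label", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), dir)
  m <- suppressMessages(read_matrix(file.path(dir, "matrix.csv")))
  cube <- unpack_headers(m, read_header_spec(file.path(dir, "header_spec.yaml")))
  maps <- lapply(Sys.glob(file.path(dir, "term-map-*.yaml")), read_term_map)
  res <- annotate_cube(cube, maps,
                       routing = c("rose cultivar" = "taxon",
                                   "organism part" = "anatomy"))
  s <- annotation_summary(res$report)
  expect_equal(sum(s$unresolved), 0L)
  expect_equal(sum(s$ambiguous), 0L)
  expect_equal(s$n_labels[s$domain == "chemical"], 61L)
  # partition invariant per domain
  expect_equal(s$resolved + s$ambiguous + s$unresolved, s$n_labels)
})

test_that("withholding chemical entries yields exactly that many unresolved", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_unresolved = 5L), dir)
  cube <- ingest_bundle(dir)
  s <- table(cube$entities$resolution)
  expect_equal(unname(s[["unresolved"]]), 5L)
  expect_equal(unname(s[["resolved"]]), 56L)
  expect_true(cube_equal(cube, truth$cube))
})

test_that("annotation is idempotent and never touches values or shape", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 6L), dir)
  m <- suppressMessages(read_matrix(file.path(dir, "matrix.csv")))
  cube <- unpack_headers(m, read_header_spec(file.path(dir, "header_spec.yaml")))
  maps <- lapply(Sys.glob(file.path(dir, "term-map-*.yaml")), read_term_map)
  routing <- c("rose cultivar" = "taxon", "organism part" = "anatomy")
  before <- tidy_table(cube)
  a1 <- annotate_cube(cube, maps, routing)$cube
  a2 <- annotate_cube(a1, maps, routing)$cube
  expect_true(cube_equal(a1, a2))
  after <- tidy_table(a1)
  expect_equal(after$value, before$value)
  expect_equal(after[, c("entity", "qtype")], before[, c("entity", "qtype")])
  expect_equal(cube_shape(a1), cube_shape(cube))
})

test_that("missing factor routing errors in strict mode only", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 4L), dir)
  cube <- unpack_headers(
    suppressMessages(read_matrix(file.path(dir, "matrix.csv"))),
    read_header_spec(file.path(dir, "header_spec.yaml")))
  maps <- lapply(Sys.glob(file.path(dir, "term-map-*.yaml")), read_term_map)
  expect_error(annotate_cube(cube, maps, routing = character()), "routed")
  expect_no_error(annotate_cube(cube, maps, routing = character(),
                                mode = "lenient"))
})

test_that("report partition matches a brute-force three-way classification", {
  m <- term_map("chemical",
                entries = list(a = list(curie = "CHEBI:1"),
                               b = list(curie = "CHEBI:2"),
                               amb = list(candidates = list(
                                 list(curie = "CHEBI:3"), list(curie = "CHEBI:4")))),
                synonyms = c(alias_a = "a"))
  set.seed(7)
  pool <- c("a", "b", "amb", "alias_a", "zzz", "qqq", "B", " A ")
  for (rep in 1:5) {
    labels <- sample(pool, sample(3:8, 1), replace = TRUE)
    res <- vapply(labels, function(l) resolve_label(l, m)$status, "")
    brute <- vapply(labels, function(l) {
      k <- normalize_label(l)
      if (!k %in% names(m$entries) && k %in% names(m$synonyms)) k <- m$synonyms[[k]]
      if (!k %in% names(m$entries)) "unresolved"
      else if (!is.null(m$entries[[k]]$candidates)) "ambiguous"
      else "resolved"
    }, "")
    expect_equal(unname(res), unname(brute))
  }
})
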