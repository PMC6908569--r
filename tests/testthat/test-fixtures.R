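test_that("default parameters plant the exemplar structure", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), dir)
  expect_equal(unname(cube_shape(truth$cube)), c(61L, 8L, 2L))
  expect_equal(truth$design$n_theoretical, 18L)
  expect_equal(truth$design$n_observed, 8L)
  m <- suppressMessages(read_matrix(truth$files[["matrix"]]))
  expect_length(m$row_labels, 61L)
  expect_length(m$column_headers, 16L)   # 8 treatments x 2 statistics
  expect_identical(nrow(check_cube(truth$cube)), 0L)
})

test_that("a 2x2 full layout observes all four combinations", {
  dir <- withr::local_tempdir()
  truth <- generate_study(
    fixture_params(cultivars = c("A", "B"), parts = c("sepal", "petal"),
                   layout = "full", n_entities = 4L), dir)
  expect_equal(truth$design$classification, "full_factorial")
  expect_equal(truth$design$n_observed, 4L)
  expect_equal(truth$design$n_theoretical, 4L)
})

test_that("identical params produce byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(fixture_params(seed = 7L), file.path(d1, "s"))
  generate_study(fixture_params(seed = 7L), file.path(d2, "s"))
  for (f in list.files(file.path(d1, "s"))) {
    expect_identical(readBin(file.path(d1, "s", f), "raw", 1e7),
                     readBin(file.path(d2, "s", f), "raw", 1e7),
                     label = f)
  }
})

test_that("SEM columns equal dispersion / sqrt(n) and are positive", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), dir)
  m <- truth$cube$measurements
  sem <- m[m$qtype == "standard error", ]
  expect_true(all(sem$value > 0))
  joined <- dplyr::left_join(sem, truth$dispersions,
                             by = c("entity", "treatment_id"))
  expect_true(all(abs(joined$value - joined$dispersion / sqrt(3)) < 1e-9))
})

test_that("invalid parameters are rejected", {
  expect_error(fixture_params(missing_rate = 1.5), "missing_rate")
  expect_error(fixture_params(cultivars = character()), "at least one level")
  expect_error(fixture_params(n_unresolved = 99L, n_entities = 10L),
               "n_unresolved")
  expect_error(generate_pair(n_shared = 99L, dir = tempfile()), "n_shared")
})

test_that("missing-cell rate produces missing measurements, not dropped rows", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 20L, missing_rate = 0.2,
                                         seed = 5L), dir)
  expect_equal(nrow(truth$cube$measurements), 20L * 8L * 2L)
  expect_gt(sum(is.na(truth$cube$measurements$value)), 0L)
  cube <- ingest_bundle(dir)
  expect_true(cube_equal(cube, truth$cube))
})

test_that("planted pair overlap arithmetic follows the parameters", {
  dir <- withr::local_tempdir()
  pr <- generate_pair(fixture_params(n_entities = 12L),
                      fixture_params(n_entities = 9L, seed = 11L),
                      n_shared = 5L, dir = dir)
  expect_equal(unname(pr$regions), c(5L, 7L, 4L))
  cmp <- compare_studies(pr$a$cube, pr$b$cube)
  expect_equal(unname(cmp$region_counts), c(5L, 7L, 4L))
  # shared = whole study when sizes equal and n_shared = size
  dir2 <- withr::local_tempdir()
  pr2 <- generate_pair(fixture_params(n_entities = 6L),
                       fixture_params(n_entities = 6L, seed = 13L),
                       n_shared = 6L, dir = dir2)
  cmp2 <- compare_studies(pr2$a$cube, pr2$b$cube)
  expect_equal(unname(cmp2$region_counts), c(6L, 0L, 0L))
  # disjoint studies
  dir3 <- withr::local_tempdir()
  pr3 <- generate_pair(fixture_params(n_entities = 4L),
                       fixture_params(n_entities = 3L, seed = 17L),
                       n_shared = 0L, dir = dir3)
  expect_equal(unname(compare_studies(pr3$a$cube, pr3$b$cube)$region_counts),
               c(0L, 4L, 3L))
})

test_that("header noise is absorbed by normalization", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 6L), dir)
  for (noise in list(list(header_case = TRUE), list(header_quotes = TRUE),
                     list(header_whitespace = TRUE))) {
    p <- tempfile(fileext = ".csv")
    mv <- generate_messy_variant(truth, noise, p)
    expect_equal(nrow(mv$manifest$expected_findings), 0L)
    cube <- unpack_headers(suppressMessages(read_matrix(p)),
                           truth$header_spec, study_id = basename(dir),
                           mode = "lenient")
    expect_equal(nrow(attr(cube, "findings")), 0L,
                 label = paste(names(noise), collapse = ","))
    maps <- lapply(Sys.glob(file.path(dir, "term-map-*.yaml")), read_term_map)
    ann <- annotate_cube(cube, maps,
                         routing = c("rose cultivar" = "taxon",
                                     "organism part" = "anatomy"))$cube
    expect_true(cube_equal(ann, truth$cube))
  }
})

test_that("injected non-numeric cells are reported one finding each", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 10L), dir)
  p <- tempfile(fileext = ".csv")
  mv <- generate_messy_variant(truth, list(non_numeric_cells = 3L), p)
  expect_equal(mv$manifest$expected_findings$count, 3L)
  cube <- unpack_headers(suppressMessages(read_matrix(p)),
                         truth$header_spec, mode = "lenient")
  f <- attr(cube, "findings")
  expect_equal(sum(f$code == "NON_NUMERIC_CELL"), 3L)
})

test_that("a ragged row is a structural error in strict reading", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 8L), dir)
  p <- tempfile(fileext = ".csv")
  mv <- generate_messy_variant(truth, list(ragged_rows = 1L), p)
  expect_true(mv$manifest$structural_error)
  expect_error(suppressMessages(read_matrix(p)), "ragged")
})

test_that("unknown perturbations are rejected by name", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 3L), dir)
  expect_error(generate_messy_variant(truth, list(gremlins = 1), tempfile()),
               "unknown perturbation")
})

test_that("the generic design generator round-trips through ingest", {
  lv <- list("light" = c("dark", "dim", "bright"),
             "genotype" = c("wt", "mut"))
  dir <- withr::local_tempdir()
  truth <- generate_design_study(lv, dir = dir)
  m <- suppressMessages(read_matrix(truth$files[["matrix"]]))
  cube <- unpack_headers(m, truth$header_spec, study_id = basename(dir))
  expect_true(cube_equal(cube, truth$cube))
  d <- infer_design(cube)
  expect_equal(d$n_theoretical, 6L)
  expect_equal(d$classification, "full_factorial")
})
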