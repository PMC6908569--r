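write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

test_that("read_matrix echoes a toy grid verbatim and reports structure", {
  p <- write_toy_csv(c("id,a — average,b — average",
                       "x,1,2", "y,3,4", "z,5,6"))
  m <- suppressMessages(read_matrix(p))
  expect_equal(m$row_labels, c("x", "y", "z"))
  expect_length(m$column_headers, 2L)
  expect_equal(m$values[2, 2], "4")
})

test_that("read_matrix rejects ragged rows and duplicate headers", {
  p <- write_toy_csv(c("id,a,b", "x,1,2", "y,3"))
  expect_error(suppressMessages(read_matrix(p)), "ragged.*line 3")
  p2 <- write_toy_csv(c("id,a ,a", "x,1,2"))
  expect_error(suppressMessages(read_matrix(p2)), "duplicate")
})

test_that("unpack_headers decomposes composed headers into levels and qtypes", {
  p <- write_toy_csv(c(
    "compound,R. chinensis 'Old Blush' sepals — average",
    "geraniol,12.5"))
  spec <- header_spec(
    factors = c("rose cultivar", "organism part"),
    rules = list(list(
      pattern = "^R\\. chinensis '(.+)' (sepals|petals) - (average|standard error)$",
      assign = c("rose cultivar", "organism part", "qtype"))),
    synonyms = c(sepals = "sepal", petals = "petal",
                 "old blush" = "Old Blush"),
    unit = "ng g-1", sample_size = 3L)
  cube <- unpack_headers(suppressMessages(read_matrix(p)), spec)
  expect_equal(cube$levels$label, c("Old Blush", "sepal"))
  expect_equal(cube$qtypes$canonical_name, "sample_mean")
  expect_equal(cube$treatments$treatment_id, "Old Blush | sepal")
  expect_equal(cube$measurements$value, 12.5)
  expect_equal(cube$measurements$sample_size, 3L)
})

test_that("a single-column matrix with default_qtype yields a 1x1x1 cube", {
  p <- write_toy_csv(c("id,sepal", "x,1"))
  spec <- header_spec(factors = "tissue",
                      rules = list(list(pattern = "^(sepal)$",
                                        assign = "tissue")),
                      default_qtype = "average", unit = "u")
  cube <- unpack_headers(suppressMessages(read_matrix(p)), spec)
  expect_equal(unname(cube_shape(cube)), c(1L, 1L, 1L))
  expect_equal(cube$qtypes$input_label, "average")
})

test_that("unmatched and ambiguous headers error in strict mode, report in lenient", {
  p <- write_toy_csv(c("id,mystery column", "x,1"))
  spec <- header_spec(factors = "tissue",
                      rules = list(list(pattern = "^(sepal)$", assign = "tissue")),
                      default_qtype = "average")
  expect_error(unpack_headers(suppressMessages(read_matrix(p)), spec),
               "matched none")
  cube <- unpack_headers(suppressMessages(read_matrix(p)), spec,
                         mode = "lenient")
  expect_equal(attr(cube, "findings")$code, "UNMATCHED_HEADER")

  spec2 <- header_spec(
    factors = "tissue",
    rules = list(list(pattern = "^(sepal)$", assign = "tissue"),
                 list(pattern = "^(sep.*)$", assign = "tissue")),
    default_qtype = "average")
  p2 <- write_toy_csv(c("id,sepal", "x,1"))
  expect_error(unpack_headers(suppressMessages(read_matrix(p2)), spec2),
               "at most one")
})

test_that("non-numeric cells carry coordinates; missing tokens do not", {
  p <- write_toy_csv(c("id,sepal,petal", "x,oops,2", "y,nd,4"))
  spec <- header_spec(factors = "tissue",
                      rules = list(list(pattern = "^(sepal|petal)$",
                                        assign = "tissue")),
                      default_qtype = "average")
  expect_error(unpack_headers(suppressMessages(read_matrix(p)), spec),
               "row 1, column 'sepal'")
  cube <- unpack_headers(suppressMessages(read_matrix(p)), spec,
                         mode = "lenient")
  f <- attr(cube, "findings")
  expect_equal(nrow(f), 1L)                       # 'nd' is a declared token
  expect_true(is.na(cube$measurements$value[cube$measurements$entity == "y" &
                                              cube$measurements$treatment_id == "sepal"]))
})

test_that("the fixture matrix unpacks to the planted cube (round trip by truth)", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), dir)
  cube <- ingest_bundle(dir)
  expect_true(cube_equal(cube, truth$cube))
  expect_equal(unname(cube_shape(cube)), c(61L, 8L, 2L))
})

test_that("tidy_table is lossless, ordered, and one row per measurement", {
  cube <- tiny_cube()
  td <- tidy_table(cube)
  expect_equal(nrow(td), 4L)
  expect_equal(names(td), c("entity", "tissue", "qtype", "value", "unit",
                            "sample_size"))
  expect_equal(td$entity, c("geraniol", "geraniol", "nerol", "nerol"))
  expect_equal(nrow(tidy_table(data_cube("empty"))), 0L)
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), dir)
  expect_equal(nrow(tidy_table(truth$cube)), 976L)   # 61 x 8 x 2
})

test_that("re-widening tidy records reproduces the original grid cell-for-cell", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 7L, seed = 9L), dir)
  m <- suppressMessages(read_matrix(file.path(dir, "matrix.csv")))
  spec <- read_header_spec(file.path(dir, "header_spec.yaml"))
  cube <- unpack_headers(m, spec)
  cmap <- attr(cube, "column_map")
  for (k in seq_len(nrow(cmap))) {
    got <- cube$measurements$value[
      cube$measurements$treatment_id == cmap$treatment_id[k] &
        cube$measurements$qtype == cmap$qtype[k]]
    expect_equal(got, as.numeric(m$values[, k]), tolerance = 1e-12)
  }
})

test_that("column permutation yields an identical cube up to canonical order", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 5L, seed = 3L), dir)
  lines <- readLines(file.path(dir, "matrix.csv"), encoding = "UTF-8")
  fields <- strsplit(lines, ",", fixed = TRUE)
  set.seed(1)
  perm <- c(1L, 1L + sample(length(fields[[1]]) - 1L))
  shuffled <- vapply(fields, function(x) paste(x[perm], collapse = ","), "")
  p2 <- file.path(dir, "shuffled.csv")
  writeLines(shuffled, p2)
  spec <- read_header_spec(file.path(dir, "header_spec.yaml"))
  c1 <- unpack_headers(suppressMessages(read_matrix(file.path(dir, "matrix.csv"))),
                       spec, study_id = "s")
  c2 <- unpack_headers(suppressMessages(read_matrix(p2)), spec, study_id = "s")
  expect_true(cube_equal(c1, c2))
})

test_that("distinct (treatment, qtype) pairs equal the matched column count", {
  dir <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), dir)
  cube <- ingest_bundle(dir)
  cmap <- attr(cube, "column_map")
  expect_equal(nrow(dplyr::distinct(cube$measurements[, c("treatment_id", "qtype")])),
               16L)
  expect_equal(nrow(cmap), 16L)
})
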