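test_that("an empty cube packages with a complete schema and zero rows", {
  dir <- withr::local_tempdir()
  cube <- data_cube("empty")
  write_package(cube, dir)
  csv <- readLines(file.path(dir, "measurements.csv"))
  expect_length(csv, 1L)   # header only
  d <- jsonlite::read_json(file.path(dir, "datapackage.json"))
  fields <- vapply(d$resources[[1]]$schema$fields, `[[`, "", "name")
  expect_true(all(c("entity_label", "qtype", "value", "unit") %in% fields))
  expect_equal(nrow(validate_package(dir)), 0L)
})

test_that("the exemplar fixture packages 976 data rows and validates clean", {
  pkg <- withr::local_tempdir()
  fx <- withr::local_tempdir()
  truth <- generate_study(fixture_params(), fx)
  write_package(truth$cube, pkg)
  csv <- readLines(file.path(pkg, "measurements.csv"))
  expect_length(csv, 977L)   # 61 x 8 x 2 data rows + header
  expect_equal(nrow(validate_package(pkg)), 0L)
})

test_that("missing cells are written as the declared empty token and survive", {
  pkg <- withr::local_tempdir()
  cube <- tiny_cube()
  cube$measurements$value[2] <- NA
  write_package(cube, pkg)
  back <- read_package(pkg)
  expect_true(cube_equal(cube, back))
  expect_equal(sum(is.na(back$measurements$value)), 1L)
})

test_that("write then read restores the cube for randomized cubes", {
  for (seed in 101:115) {
    pkg <- tempfile("pkg")
    cube <- random_cube(seed)
    write_package(cube, pkg)
    expect_true(cube_equal(cube, read_package(pkg)), label = paste("seed", seed))
    unlink(pkg, recursive = TRUE)
  }
})

test_that("double-write is byte-identical for every writer", {
  fx <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 9L), fx)
  d1 <- file.path(fx, "p1"); d2 <- file.path(fx, "p2")
  write_package(truth$cube, d1)
  write_package(truth$cube, d2)
  for (f in c("measurements.csv", "datapackage.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  i1 <- write_isatab_stub(list(identifier = "S1", title = "T"),
                          "p1", file.path(fx, "i1"))
  i2 <- write_isatab_stub(list(identifier = "S1", title = "T"),
                          "p1", file.path(fx, "i2"))
  expect_identical(readLines(i1), readLines(i2))
})

test_that("a corrupted number cell is a validation error naming the cell", {
  pkg <- withr::local_tempdir()
  write_package(tiny_cube(), pkg)
  csv <- readLines(file.path(pkg, "measurements.csv"))
  csv[2] <- sub("1\\.5", "not-a-number", csv[2])
  writeLines(csv, file.path(pkg, "measurements.csv"))
  expect_error(read_package(pkg), "row 1.*number")
  rep <- validate_package(pkg)
  expect_equal(rep$code, "TYPE_VIOLATION")
  expect_equal(rep$row, 1L)
  expect_equal(rep$field, "value")
})

test_that("every injected corruption class is detected", {
  base <- withr::local_tempdir()
  write_package(tiny_cube(), base)

  # three corrupted cells -> exactly three findings
  p <- file.path(base, "three"); dir.create(p)
  file.copy(file.path(base, "datapackage.json"), p)
  csv <- readLines(file.path(base, "measurements.csv"))
  csv[2] <- sub("1\\.5", "bad1", csv[2])
  csv[3] <- sub("2\\.5", "bad2", csv[3])
  csv[4] <- sub(",3,", ",3.7,", csv[4])   # fractional value in integer field
  writeLines(csv, file.path(p, "measurements.csv"))
  rep <- validate_package(p)
  expect_equal(nrow(rep), 3L)
  expect_true(all(rep$code == "TYPE_VIOLATION"))

  # arity: drop a column
  p2 <- file.path(base, "arity"); dir.create(p2)
  file.copy(file.path(base, "datapackage.json"), p2)
  writeLines(sub(",[^,]*$", "", readLines(file.path(base, "measurements.csv"))),
             file.path(p2, "measurements.csv"))
  expect_true("SCHEMA_ARITY" %in% validate_package(p2)$code)

  # token discipline: undeclared missing marker in a number field
  p3 <- file.path(base, "token"); dir.create(p3)
  file.copy(file.path(base, "datapackage.json"), p3)
  csv3 <- readLines(file.path(base, "measurements.csv"))
  csv3[2] <- sub("1\\.5", "n.d.", csv3[2])
  writeLines(csv3, file.path(p3, "measurements.csv"))
  expect_true("TYPE_VIOLATION" %in% validate_package(p3)$code)

  # IRI syntax in the schema
  p4 <- file.path(base, "iri"); dir.create(p4)
  file.copy(file.path(base, "measurements.csv"), p4)
  d <- readLines(file.path(base, "datapackage.json"))
  d <- sub('"rdfType": "http://', '"rdfType": "not-an-iri://', d)
  writeLines(d, file.path(p4, "datapackage.json"))
  expect_true("BAD_TERM_IRI" %in% validate_package(p4)$code)

  # CURIE syntax in identifier columns
  p5 <- file.path(base, "curie"); dir.create(p5)
  file.copy(file.path(base, "datapackage.json"), p5)
  fx <- withr::local_tempdir()
  truth <- generate_study(fixture_params(n_entities = 3L), fx)
  write_package(truth$cube, file.path(base, "cur"))
  csv5 <- readLines(file.path(base, "cur", "measurements.csv"))
  csv5[2] <- sub("CHEBI:900001", "CHEBI_900001x y", csv5[2])
  p5 <- file.path(base, "cur")
  writeLines(csv5, file.path(p5, "measurements.csv"))
  expect_true("BAD_CURIE" %in% validate_package(p5)$code)

  # absent descriptor is a single fatal finding
  p6 <- file.path(base, "nodesc"); dir.create(p6)
  rep6 <- validate_package(p6)
  expect_equal(nrow(rep6), 1L)
  expect_equal(rep6$severity, "fatal")
})

test_that("a package from an independent minimal writer reads identically", {
  # write the same logical content with plain base R, following the same
  # descriptor rules, and check the reader reconstructs an equal cube
  pkg <- withr::local_tempdir()
  cube <- tiny_cube()
  write_package(cube, pkg)
  alt <- withr::local_tempdir()
  tbl <- utils::read.csv(file.path(pkg, "measurements.csv"),
                         check.names = FALSE, colClasses = "character")
  utils::write.csv(tbl, file.path(alt, "measurements.csv"), row.names = FALSE,
                   quote = which(vapply(tbl, function(x)
                     any(grepl("[,\"]", x)), TRUE)))
  file.copy(file.path(pkg, "datapackage.json"), alt)
  expect_true(cube_equal(read_package(alt), cube))
})

test_that("the ISA-Tab stub references each package once, deterministically", {
  dir <- withr::local_tempdir()
  p1 <- write_isatab_stub(list(identifier = "rose-study", title = "Rose"),
                          "pkg/a", file.path(dir, "one"))
  lines <- readLines(p1)
  expect_equal(sum(grepl("Comment\\[Tabular Data Package\\]", lines)), 1L)
  expect_true(any(grepl("^ONTOLOGY SOURCE REFERENCE$", lines)))
  expect_true(any(grepl("^INVESTIGATION$", lines)))
  expect_true(any(grepl("^STUDY ASSAYS$", lines)))
  p2 <- write_isatab_stub(list(identifier = "rose-study", title = "Rose"),
                          c("pkg/a", "pkg/b"), file.path(dir, "two"))
  expect_equal(sum(grepl("Comment\\[Tabular Data Package\\]", readLines(p2))), 2L)
  expect_error(write_isatab_stub(list(title = "no id"), "p", dir),
               "identifier")
})
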