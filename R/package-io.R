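# Tabular Data Package writer / reader / validator, plus a minimal ISA-Tab
# investigation stub. One denormalized `measurements` resource carries the
# whole tidy cube; cube-level structure (factor and level order, qtype
# definitions, provenance) travels in a custom `cube` descriptor block so
# the write -> read round trip is lossless.

.id_cols <- c(entity_input_label = "string", entity_label = "string",
              entity_curie = "string", entity_iri = "string",
              entity_term_label = "string", entity_inchi = "string",
              entity_resolution = "string")

# RFC 4180 field quoting, LF line endings, fixed formatting -> byte
# determinism for identical cubes.
.csv_quote <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) "" else trimws(formatC(v, digits = 15, format = "g"))
  }, ""))
  out
}

.write_csv_lines <- function(tbl, path) {
  header <- paste(.csv_quote(names(tbl)), collapse = ",")
  cols <- lapply(tbl, function(col) {
    if (is.numeric(col) && !is.integer(col)) .fmt_num(col)
    else if (is.integer(col)) ifelse(is.na(col), "", as.character(col))
    else .csv_quote(as.character(col))
  })
  body <- if (nrow(tbl)) do.call(paste, c(cols, sep = ",")) else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

.full_tidy <- function(cube) {
  base <- tidy_table(cube)
  ent <- cube$entities
  idx <- match(base$entity, ent$normalized_label)
  tibble::tibble(
    entity_input_label = ent$input_label[idx],
    entity_label = base$entity,
    entity_curie = ent$curie[idx],
    entity_iri = ent$iri[idx],
    entity_term_label = ent$term_label[idx],
    entity_inchi = ent$inchi[idx],
    entity_resolution = ent$resolution[idx]) |>
    dplyr::bind_cols(base[, setdiff(names(base), "entity"), drop = FALSE]) |>
    dplyr::bind_cols(tibble::tibble(
      qtype_canonical = cube$qtypes$canonical_name[
        match(base$qtype, cube$qtypes$input_label)],
      replicate_semantics = cube$measurements$replicate_semantics[
        match(paste(base$entity, do.call(paste, c(base[cube$factors$name], sep = " | ")),
                    base$qtype),
              paste(cube$measurements$entity, cube$measurements$treatment_id,
                    cube$measurements$qtype))])) |>
    (\(tbl) tbl[, c(names(.id_cols), cube$factors$name, "qtype",
                    "qtype_canonical", "value", "unit", "sample_size",
                    "replicate_semantics"), drop = FALSE])()
}

.schema_fields <- function(cube) {
  f <- function(name, type, rdf = NULL, title = NULL) {
    fld <- list(name = name, type = type)
    if (!is.null(rdf) && !is.na(rdf)) fld$rdfType <- rdf
    if (!is.null(title)) fld$title <- title
    fld
  }
  fields <- list(
    f("entity_input_label", "string", title = "verbatim compound label from the source matrix"),
    f("entity_label", "string", title = "normalized compound label"),
    f("entity_curie", "string", title = "chemical entity CURIE (ChEBI)",
      rdf = "http://purl.obolibrary.org/obo/CHEBI_23367"),
    f("entity_iri", "string"),
    f("entity_term_label", "string", title = "ontology term label"),
    f("entity_inchi", "string", title = "InChI descriptor"),
    f("entity_resolution", "string"))
  for (i in seq_len(nrow(cube$factors))) {
    fields[[length(fields) + 1L]] <-
      f(cube$factors$name[i], "string", rdf = cube$factors$iri[i],
        title = paste("factor level of independent variable",
                      cube$factors$name[i]))
  }
  c(fields, list(
    f("qtype", "string", title = "quantitation type as reported",
      rdf = "http://purl.obolibrary.org/obo/IAO_0000109"),
    f("qtype_canonical", "string"),
    f("value", "number"),
    f("unit", "string"),
    f("sample_size", "integer",
      rdf = "http://purl.obolibrary.org/obo/STATO_0000088"),
    f("replicate_semantics", "string")))
}

.cube_block <- function(cube) {
  list(
    study_id = cube$study_id,
    factors = lapply(seq_len(nrow(cube$factors)), function(i) {
      f <- cube$factors$name[i]
      lv <- cube$levels[cube$levels$factor_name == f, , drop = FALSE]
      list(name = f,
           curie = cube$factors$curie[i], iri = cube$factors$iri[i],
           term_label = cube$factors$term_label[i],
           levels = lapply(seq_len(nrow(lv)), function(k)
             list(label = lv$label[k], curie = lv$curie[k],
                  iri = lv$iri[k], term_label = lv$term_label[k])))
    }),
    qtypes = lapply(seq_len(nrow(cube$qtypes)), function(i)
      as.list(cube$qtypes[i, , drop = FALSE])),
    provenance = as.list(cube$provenance))
}

#' Write a cube as a Tabular Data Package
#'
#' Emits `datapackage.json` (name, license, resource list, table schema
#' with per-field types and term IRIs, declared missing-value tokens) and
#' a single `measurements.csv` resource holding the denormalized tidy
#' table. Output is deterministic: the same cube produces byte-identical
#' files (fixed field order, fixed number formatting, LF line endings,
#' missing cells written as the empty string).
#'
#' @param cube A [data_cube()] (annotation optional).
#' @param dir Output directory (created if needed).
#' @param name Package name (lowercase, hyphenated).
#' @param title Optional human title.
#' @return The descriptor list, invisibly.
#' @export
write_package <- function(cube, dir, name = "fairified-study", title = NULL) {
  stopifnot(inherits(cube, "data_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- .full_tidy(cube)
  .write_csv_lines(tbl, file.path(dir, "measurements.csv"))
  descriptor <- list(
    profile = "tabular-data-package",
    name = name,
    title = title %||% paste("FAIRified results matrix for study", cube$study_id),
    licenses = list(list(name = "CC-BY-4.0",
                         title = "Creative Commons Attribution 4.0",
                         path = "https://creativecommons.org/licenses/by/4.0/")),
    resources = list(list(
      profile = "tabular-data-resource",
      name = "measurements",
      path = "measurements.csv",
      format = "csv",
      encoding = "utf-8",
      dialect = list(delimiter = ",", quoteChar = "\"", lineTerminator = "\n"),
      schema = list(fields = .schema_fields(cube),
                    missingValues = list("")))),
    cube = .cube_block(cube))
  jsonlite::write_json(descriptor, file.path(dir, "datapackage.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(descriptor)
}

.read_descriptor <- function(dir) {
  dp <- file.path(dir, "datapackage.json")
  if (!file.exists(dp)) stop("no datapackage.json in ", dir, call. = FALSE)
  jsonlite::read_json(dp)
}

.parse_typed_column <- function(raw, type, field, missing_values) {
  raw_chr <- as.character(raw)
  miss <- raw_chr %in% missing_values | is.na(raw_chr)
  if (type == "number" || type == "integer") {
    parsed <- suppressWarnings(as.numeric(raw_chr))
    bad <- which(!miss & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("type violation in field '%s': row %d holds '%s' where a %s was declared",
                   field, bad[1], raw_chr[bad[1]], type), call. = FALSE)
    }
    parsed[miss] <- NA_real_
    if (type == "integer") return(as.integer(parsed))
    return(parsed)
  }
  raw_chr[miss] <- NA_character_
  raw_chr
}

#' Read a Tabular Data Package back into a cube
#'
#' The inverse of [write_package()]: `read_package(write_package(cube))`
#' equals the original cube up to canonical ordering. Schema/data
#' mismatches (wrong column set, type violations) are errors naming the
#' offending row and field.
#'
#' @param dir Directory containing `datapackage.json`.
#' @return A [data_cube()].
#' @export
read_package <- function(dir) {
  d <- .read_descriptor(dir)
  res <- purrr::detect(d$resources, ~ .x$name == "measurements")
  if (is.null(res)) stop("package has no 'measurements' resource", call. = FALSE)
  path <- file.path(dir, res$path)
  if (!file.exists(path)) stop("resource data file missing: ", res$path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  fields <- res$schema$fields
  fnames <- vapply(fields, `[[`, "", "name")
  if (!identical(names(raw), fnames)) {
    stop(sprintf("schema/data mismatch: data columns (%s) differ from schema fields (%s)",
                 paste(names(raw), collapse = ", "),
                 paste(fnames, collapse = ", ")), call. = FALSE)
  }
  missing_values <- unlist(res$schema$missingValues) %||% ""
  tbl <- tibble::as_tibble(raw)
  for (f in fields) {
    tbl[[f$name]] <- .parse_typed_column(raw[[f$name]], f$type, f$name,
                                         missing_values)
  }

  cb <- d$cube
  factors <- factor_table(tibble::tibble(
    name = vapply(cb$factors, `[[`, "", "name"),
    curie = vapply(cb$factors, function(x) x$curie %||% NA_character_, ""),
    iri = vapply(cb$factors, function(x) x$iri %||% NA_character_, ""),
    term_label = vapply(cb$factors, function(x) x$term_label %||% NA_character_, "")))
  levels <- dplyr::bind_rows(lapply(cb$factors, function(fc) {
    tibble::tibble(
      factor_name = fc$name,
      label = vapply(fc$levels, `[[`, "", "label"),
      curie = vapply(fc$levels, function(x) x$curie %||% NA_character_, ""),
      iri = vapply(fc$levels, function(x) x$iri %||% NA_character_, ""),
      term_label = vapply(fc$levels, function(x) x$term_label %||% NA_character_, ""))
  }))
  qtypes <- dplyr::bind_rows(lapply(cb$qtypes, function(q)
    tibble::as_tibble(lapply(q, function(v) v %||% NA))))
  qtypes <- qtype_table(qtypes)

  ent <- dplyr::distinct(tbl[, names(.id_cols)])
  entities <- entity_table(tibble::tibble(
    input_label = ent$entity_input_label,
    normalized_label = ent$entity_label,
    curie = ent$entity_curie, iri = ent$entity_iri,
    term_label = ent$entity_term_label,
    inchi = ent$entity_inchi, resolution = ent$entity_resolution))

  fac_names <- factors$name
  tid <- do.call(paste, c(unname(as.list(tbl[, fac_names, drop = FALSE])),
                          sep = " | "))
  trt <- dplyr::distinct(dplyr::bind_cols(
    tibble::tibble(treatment_id = tid, status = "observed"),
    tbl[, fac_names, drop = FALSE]))
  measurements <- tibble::tibble(
    entity = tbl$entity_label, treatment_id = tid, qtype = tbl$qtype,
    value = tbl$value, unit = tbl$unit,
    sample_size = as.integer(tbl$sample_size),
    replicate_semantics = tbl$replicate_semantics)
  data_cube(study_id = cb$study_id %||% "study", entities = entities,
            factors = factors, levels = levels, treatments = trt,
            qtypes = qtypes, measurements = measurements,
            provenance = unlist(cb$provenance) %||% character())
}

.finding <- function(severity, code, message, resource = NA_character_,
                     row = NA_integer_, field = NA_character_) {
  tibble::tibble(severity = severity, code = code, message = message,
                 resource = resource, row = as.integer(row), field = field)
}

#' Validate a data package on disk
#'
#' Checks descriptor well-formedness, schema/data arity, per-cell type
#' conformance, missing-token discipline, CURIE syntax in identifier
#' columns and term-IRI syntax in the schema. All findings are returned;
#' nothing is raised.
#'
#' @param dir Package directory.
#' @return Tibble of findings (`severity`, `code`, `message`, `resource`,
#'   `row`, `field`); zero rows for a valid package.
#' @export
validate_package <- function(dir) {
  no_findings <- .finding(character(), character(), character())[0, ]
  if (!dir.exists(dir)) {
    return(.finding("fatal", "NO_DIRECTORY", paste0("package directory not found: ", dir)))
  }
  dp <- file.path(dir, "datapackage.json")
  if (!file.exists(dp)) {
    return(.finding("fatal", "NO_DESCRIPTOR", "datapackage.json is missing"))
  }
  d <- tryCatch(jsonlite::read_json(dp), error = function(e) e)
  if (inherits(d, "error")) {
    return(.finding("fatal", "BAD_DESCRIPTOR",
                    paste0("descriptor is not parseable JSON: ", conditionMessage(d))))
  }
  out <- list()
  push <- function(...) out[[length(out) + 1L]] <<- .finding(...)
  if (is.null(d$resources) || length(d$resources) == 0L) {
    push("fatal", "NO_RESOURCES", "descriptor declares no resources")
    return(dplyr::bind_rows(out))
  }
  for (res in d$resources) {
    rname <- res$name %||% "<unnamed>"
    path <- file.path(dir, res$path %||% "")
    if (!file.exists(path)) {
      push("error", "MISSING_DATA_FILE",
           paste0("resource data file not found: ", res$path), rname)
      next
    }
    fields <- res$schema$fields
    fnames <- vapply(fields, `[[`, "", "name")
    for (f in fields) {
      if (!is.null(f$rdfType) && !grepl("^https?://", f$rdfType)) {
        push("error", "BAD_TERM_IRI",
             sprintf("field '%s' declares a non-resolvable term IRI: '%s'",
                     f$name, f$rdfType), rname, field = f$name)
      }
    }
    raw <- tryCatch(
      utils::read.csv(path, colClasses = "character", check.names = FALSE,
                      na.strings = NULL),
      error = function(e) e)
    if (inherits(raw, "error")) {
      push("fatal", "UNREADABLE_DATA", conditionMessage(raw), rname)
      next
    }
    if (!identical(names(raw), fnames)) {
      push("error", "SCHEMA_ARITY",
           sprintf("data columns (%d: %s) do not match schema fields (%d: %s)",
                   length(names(raw)), paste(names(raw), collapse = ", "),
                   length(fnames), paste(fnames, collapse = ", ")), rname)
      next
    }
    missing_values <- unlist(res$schema$missingValues) %||% ""
    for (f in fields) {
      if (!f$type %in% c("number", "integer")) next
      col <- as.character(raw[[f$name]])
      miss <- col %in% missing_values
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!miss & is.na(parsed))
      for (b in bad) {
        push("error", "TYPE_VIOLATION",
             sprintf("row %d, field '%s': '%s' is not a %s and not a declared missing token",
                     b, f$name, col[b], f$type), rname, b, f$name)
      }
      if (f$type == "integer") {
        frac <- which(!miss & !is.na(parsed) & parsed != floor(parsed))
        for (b in frac) {
          push("error", "TYPE_VIOLATION",
               sprintf("row %d, field '%s': '%s' is not an integer", b, f$name, col[b]),
               rname, b, f$name)
        }
      }
    }
    if ("entity_curie" %in% names(raw)) {
      cu <- raw$entity_curie
      bad <- which(!cu %in% missing_values & !grepl(.curie_regex, cu))
      for (b in bad) {
        push("error", "BAD_CURIE",
             sprintf("row %d: malformed CURIE '%s'", b, cu[b]), rname, b,
             "entity_curie")
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else no_findings
}

#' Write a minimal ISA-Tab investigation stub
#'
#' A tab-delimited `i_<identifier>.txt` with ontology-source,
#' investigation, study and study-assay sections; each data package is
#' referenced by one `Comment[Tabular Data Package]` row. The stub is an
#' investigation-level pointer only, not a full ISA-Tab study.
#'
#' @param metadata List with mandatory `identifier` and `title`, optional
#'   `description`.
#' @param packages Character vector of data-package paths to reference.
#' @param dir Output directory.
#' @return Path of the written file, invisibly.
#' @export
write_isatab_stub <- function(metadata, packages, dir) {
  mandatory <- c("identifier", "title")
  absent <- mandatory[!mandatory %in% names(metadata) |
                        vapply(metadata[mandatory], function(x)
                          is.null(x) || !nzchar(x %||% ""), TRUE)]
  if (length(absent)) {
    stop("missing mandatory study metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- function(...) paste(vapply(list(...), function(x)
    paste0("\"", x, "\""), ""), collapse = "\t")
  lines <- c(
    "ONTOLOGY SOURCE REFERENCE",
    paste("Term Source Name", q("CHEBI"), q("NCBITAXON"), q("PO"), q("STATO"), sep = "\t"),
    paste("Term Source File", q(""), q(""), q(""), q(""), sep = "\t"),
    "INVESTIGATION",
    paste("Investigation Identifier", q(metadata$identifier), sep = "\t"),
    paste("Investigation Title", q(metadata$title), sep = "\t"),
    paste("Investigation Description", q(metadata$description %||% ""), sep = "\t"),
    "STUDY",
    paste("Study Identifier", q(metadata$identifier), sep = "\t"),
    paste("Study Title", q(metadata$title), sep = "\t"),
    "STUDY ASSAYS",
    paste("Study Assay Measurement Type", q("metabolite profiling"), sep = "\t"))
  for (p in packages) {
    lines <- c(lines, paste("Comment[Tabular Data Package]", q(p), sep = "\t"))
  }
  path <- file.path(dir, paste0("i_", gsub("[^A-Za-z0-9_.-]", "_",
                                           metadata$identifier), ".txt"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
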