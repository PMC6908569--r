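#' @importFrom rlang .data %||%
#' @import tibble
NULL

# Column contracts shared across the package. Every table in a cube carries
# exactly these columns, in this order; constructors pad absent ones.
.entity_cols <- c("input_label", "normalized_label", "curie", "iri",
                  "term_label", "inchi", "resolution")
.factor_cols <- c("name", "curie", "iri", "term_label")
.level_cols <- c("factor_name", "label", "curie", "iri", "term_label")
.qtype_cols <- c("input_label", "canonical_name", "requires_sample_size",
                 "curie", "iri", "term_label")
.meas_cols <- c("entity", "treatment_id", "qtype", "value", "unit",
                "sample_size", "replicate_semantics")

.curie_regex <- "^[A-Za-z][A-Za-z0-9_.]*:[A-Za-z0-9_.-]+$"

#' Construct an ontology term
#'
#' A term is an opaque (label, CURIE, IRI) triple; no reasoning is performed
#' on it anywhere in the package.
#'
#' @param label Human-readable label.
#' @param curie Compact identifier `PREFIX:ACCESSION` (exactly one colon).
#' @param iri Resolvable IRI; derived from the CURIE via the OBO PURL
#'   pattern when omitted.
#' @param source Ontology short name (e.g. `"CHEBI"`); defaults to the
#'   CURIE prefix.
#' @return A list of class `ontology_term`.
#' @export
ontology_term <- function(label, curie, iri = NULL, source = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!grepl(.curie_regex, curie)) {
    stop("malformed CURIE (expected PREFIX:ACCESSION): ", curie, call. = FALSE)
  }
  prefix <- sub(":.*$", "", curie)
  structure(
    list(label = label, curie = curie,
         iri = iri %||% curie_to_iri(curie),
         source = source %||% prefix),
    class = "ontology_term")
}

#' Expand a CURIE to an IRI using the OBO PURL pattern
#'
#' @param curie A `PREFIX:ACCESSION` string.
#' @param prefixes Optional named character vector mapping prefixes to IRI
#'   stems; unlisted prefixes fall back to
#'   `http://purl.obolibrary.org/obo/PREFIX_`.
#' @return An IRI string.
#' @export
curie_to_iri <- function(curie, prefixes = NULL) {
  parts <- strsplit(curie, ":", fixed = TRUE)[[1]]
  if (!is.null(prefixes) && parts[1] %in% names(prefixes)) {
    return(paste0(prefixes[[parts[1]]], parts[2]))
  }
  paste0("http://purl.obolibrary.org/obo/", parts[1], "_", parts[2])
}

.pad_tbl <- function(tbl, cols, types) {
  tbl <- tibble::as_tibble(tbl)
  for (i in seq_along(cols)) {
    if (!cols[i] %in% names(tbl)) tbl[[cols[i]]] <- types[[i]]
  }
  tbl[, cols, drop = FALSE]
}

.chr <- NA_character_
.dbl <- NA_real_
.int <- NA_integer_

entity_table <- function(tbl = NULL) {
  if (is.null(tbl)) tbl <- tibble::tibble(input_label = character())
  tbl <- .pad_tbl(tbl, .entity_cols,
                  list(.chr, .chr, .chr, .chr, .chr, .chr, .chr))
  tbl$resolution[is.na(tbl$resolution)] <- "unresolved"
  if (any(is.na(tbl$normalized_label))) {
    idx <- is.na(tbl$normalized_label)
    tbl$normalized_label[idx] <- normalize_label(tbl$input_label[idx])
  }
  tbl
}

factor_table <- function(tbl = NULL) {
  if (is.null(tbl)) tbl <- tibble::tibble(name = character())
  .pad_tbl(tbl, .factor_cols, list(.chr, .chr, .chr, .chr))
}

level_table <- function(tbl = NULL) {
  if (is.null(tbl)) tbl <- tibble::tibble(factor_name = character(),
                                          label = character())
  .pad_tbl(tbl, .level_cols, list(.chr, .chr, .chr, .chr, .chr))
}

qtype_table <- function(tbl = NULL) {
  if (is.null(tbl)) tbl <- tibble::tibble(input_label = character())
  tbl <- .pad_tbl(tbl, .qtype_cols, list(.chr, .chr, NA, .chr, .chr, .chr))
  tbl$canonical_name[is.na(tbl$canonical_name)] <- "other"
  tbl$requires_sample_size[is.na(tbl$requires_sample_size)] <-
    tbl$canonical_name[is.na(tbl$requires_sample_size)] %in%
    c("sample_mean", "standard_error_of_mean")
  tbl
}

measurement_table <- function(tbl = NULL) {
  if (is.null(tbl)) {
    tbl <- tibble::tibble(entity = character(), treatment_id = character(),
                          qtype = character(), value = double())
  }
  tbl <- .pad_tbl(tbl, .meas_cols,
                  list(.chr, .chr, .chr, .dbl, .chr, .int, .chr))
  tbl$replicate_semantics[is.na(tbl$replicate_semantics)] <- "unspecified"
  tbl$sample_size <- as.integer(tbl$sample_size)
  tbl
}

#' Build a treatment identifier from an ordered tuple of level labels
#'
#' @param ... Character vectors of level labels, one per factor, in factor
#'   declaration order (vectorised).
#' @return Character vector of identifiers (`" | "`-joined tuples).
#' @export
treatment_id <- function(...) {
  do.call(paste, c(list(...), sep = " | "))
}

#' Construct a data cube
#'
#' The central container: molecular entities x observed treatments x
#' quantitation types, with one measurement record per cell. All component
#' tables are coerced to the package's fixed column contracts; missing
#' annotation columns are padded with `NA`.
#'
#' @param study_id Study identifier string.
#' @param entities Tibble with at least `input_label`.
#' @param factors Tibble with at least `name`, one row per factor, in
#'   declaration order.
#' @param levels Tibble with `factor_name`, `label`; row order within a
#'   factor is the level order.
#' @param treatments Tibble with `treatment_id`, `status`, and one column
#'   per factor name holding level labels.
#' @param qtypes Tibble with at least `input_label`; `canonical_name` is one
#'   of `sample_mean`, `standard_error_of_mean`, `other`.
#' @param measurements Tibble with `entity` (normalized entity label),
#'   `treatment_id`, `qtype` (qtype input label), `value`, `unit`,
#'   `sample_size`, `replicate_semantics`.
#' @param provenance Character vector of free-text notes.
#' @return An object of class `data_cube`.
#' @seealso [check_cube()], [cube_shape()], [tidy_table()]
#' @export
data_cube <- function(study_id = "study", entities = NULL, factors = NULL,
                      levels = NULL, treatments = NULL, qtypes = NULL,
                      measurements = NULL, provenance = character()) {
  factors <- factor_table(factors)
  if (is.null(treatments)) {
    treatments <- tibble::tibble(treatment_id = character(),
                                 status = character())
    for (f in factors$name) treatments[[f]] <- character()
  } else {
    treatments <- tibble::as_tibble(treatments)
    if (!"status" %in% names(treatments)) treatments$status <- "observed"
  }
  structure(
    list(study_id = study_id,
         entities = entity_table(entities),
         factors = factors,
         levels = level_table(levels),
         treatments = treatments,
         qtypes = qtype_table(qtypes),
         measurements = measurement_table(measurements),
         provenance = provenance),
    class = "data_cube")
}

#' @export
print.data_cube <- function(x, ...) {
  shp <- cube_shape(x)
  cat(sprintf("<data_cube> study '%s': %d entities x %d treatments x %d quantitation types\n",
              x$study_id, shp[1], shp[2], shp[3]))
  cat(sprintf("  factors: %s\n", if (nrow(x$factors)) {
    paste(sprintf("%s (%d levels)", x$factors$name,
                  tabulate(factor(x$levels$factor_name, x$factors$name),
                           nrow(x$factors))), collapse = ", ")
  } else "none"))
  cat(sprintf("  measurements: %d\n", nrow(x$measurements)))
  invisible(x)
}

#' Cube dimensions
#'
#' @param cube A [data_cube()].
#' @return Integer vector `(n_entities, n_observed_treatments, n_qtypes)`.
#' @export
cube_shape <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  c(n_entities = nrow(cube$entities),
    n_treatments = sum(cube$treatments$status == "observed"),
    n_qtypes = nrow(cube$qtypes))
}

.violation <- function(code, message) {
  tibble::tibble(code = code, message = message)
}

#' Check the structural invariants of a cube
#'
#' Runs every structural consistency rule (reference integrity, uniqueness
#' keys, CURIE syntax, sample-size discipline, cell-count bound) and reports
#' all violations. The cube is never mutated and nothing is raised:
#' an empty report means a valid cube.
#'
#' @param cube A [data_cube()].
#' @return Tibble with columns `code`, `message`; zero rows when valid.
#' @export
check_cube <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  v <- list()
  ent <- cube$entities
  dup <- ent$normalized_label[duplicated(ent$normalized_label)]
  for (d in unique(dup)) {
    v[[length(v) + 1L]] <- .violation(
      "DUPLICATE_ENTITY", paste0("normalized entity label not unique: '", d, "'"))
  }
  bad_res <- ent$resolution == "resolved" & is.na(ent$curie)
  for (l in ent$input_label[bad_res]) {
    v[[length(v) + 1L]] <- .violation(
      "RESOLVED_WITHOUT_TERM", paste0("entity marked resolved but has no term: '", l, "'"))
  }
  bad_unres <- ent$resolution == "unresolved" & (!is.na(ent$curie) | !is.na(ent$inchi))
  for (l in ent$input_label[bad_unres]) {
    v[[length(v) + 1L]] <- .violation(
      "UNRESOLVED_WITH_TERM", paste0("entity marked unresolved but carries identifiers: '", l, "'"))
  }
  for (cu in stats::na.omit(c(ent$curie, cube$levels$curie, cube$factors$curie,
                              cube$qtypes$curie))) {
    if (!grepl(.curie_regex, cu)) {
      v[[length(v) + 1L]] <- .violation("BAD_CURIE", paste0("malformed CURIE: '", cu, "'"))
    }
  }
  # factors and levels
  for (f in cube$factors$name) {
    if (!any(cube$levels$factor_name == f)) {
      v[[length(v) + 1L]] <- .violation(
        "FACTOR_WITHOUT_LEVELS", paste0("factor has no levels: '", f, "'"))
    }
  }
  orph <- setdiff(unique(cube$levels$factor_name), cube$factors$name)
  for (f in orph) {
    v[[length(v) + 1L]] <- .violation(
      "ORPHAN_LEVEL", paste0("levels reference undeclared factor: '", f, "'"))
  }
  key <- paste(cube$levels$factor_name, cube$levels$label, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    v[[length(v) + 1L]] <- .violation(
      "DUPLICATE_LEVEL", paste0("duplicate level within factor: '",
                                sub("\r", "' / '", k), "'"))
  }
  # treatments: one level per factor, levels known, ids unique
  trt <- cube$treatments
  missing_cols <- setdiff(cube$factors$name, names(trt))
  for (f in missing_cols) {
    v[[length(v) + 1L]] <- .violation(
      "TREATMENT_BAD_ARITY", paste0("treatments lack a column for factor: '", f, "'"))
  }
  for (f in intersect(cube$factors$name, names(trt))) {
    lv <- cube$levels$label[cube$levels$factor_name == f]
    unknown <- setdiff(stats::na.omit(unique(trt[[f]])), lv)
    for (u in unknown) {
      v[[length(v) + 1L]] <- .violation(
        "UNKNOWN_LEVEL", paste0("treatment uses undeclared level '", u,
                                "' of factor '", f, "'"))
    }
    if (any(is.na(trt[[f]]))) {
      v[[length(v) + 1L]] <- .violation(
        "TREATMENT_BAD_ARITY", paste0("treatment missing a level for factor '", f, "'"))
    }
  }
  for (d in unique(trt$treatment_id[duplicated(trt$treatment_id)])) {
    v[[length(v) + 1L]] <- .violation(
      "DUPLICATE_TREATMENT", paste0("duplicate treatment id: '", d, "'"))
  }
  # qtypes
  qt <- cube$qtypes
  bad_q <- qt$canonical_name == "sample_mean" & !qt$requires_sample_size
  for (l in qt$input_label[bad_q]) {
    v[[length(v) + 1L]] <- .violation(
      "MEAN_WITHOUT_N", paste0("sample-mean qtype must require a sample size: '", l, "'"))
  }
  for (d in unique(qt$input_label[duplicated(qt$input_label)])) {
    v[[length(v) + 1L]] <- .violation(
      "DUPLICATE_QTYPE", paste0("duplicate quantitation type: '", d, "'"))
  }
  # measurements: reference integrity, uniqueness, sample-size rule, bound
  m <- cube$measurements
  for (e in setdiff(unique(m$entity), ent$normalized_label)) {
    v[[length(v) + 1L]] <- .violation(
      "DANGLING_ENTITY", paste0("measurement references unknown entity: '", e, "'"))
  }
  observed_ids <- trt$treatment_id[trt$status == "observed"]
  for (t in setdiff(unique(m$treatment_id), observed_ids)) {
    v[[length(v) + 1L]] <- .violation(
      "DANGLING_TREATMENT", paste0("measurement references treatment not observed in cube: '", t, "'"))
  }
  for (q in setdiff(unique(m$qtype), qt$input_label)) {
    v[[length(v) + 1L]] <- .violation(
      "DANGLING_QTYPE", paste0("measurement references unknown quantitation type: '", q, "'"))
  }
  mkey <- paste(m$entity, m$treatment_id, m$qtype, sep = "\r")
  for (k in unique(mkey[duplicated(mkey)])) {
    v[[length(v) + 1L]] <- .violation(
      "DUPLICATE_MEASUREMENT",
      paste0("duplicate (entity, treatment, qtype) cell: '",
             gsub("\r", "' / '", k), "'"))
  }
  req <- stats::setNames(qt$requires_sample_size, qt$input_label)
  needs_n <- !is.na(m$value) & m$qtype %in% qt$input_label & req[m$qtype] &
    is.na(m$sample_size)
  for (i in which(needs_n)) {
    v[[length(v) + 1L]] <- .violation(
      "MISSING_SAMPLE_SIZE",
      sprintf("measurement (%s, %s, %s) has a value but no sample size",
              m$entity[i], m$treatment_id[i], m$qtype[i]))
  }
  bound <- nrow(ent) * length(observed_ids) * nrow(qt)
  if (nrow(m) > bound) {
    v[[length(v) + 1L]] <- .violation(
      "EXCESS_MEASUREMENTS",
      sprintf("%d measurements exceed the %d-cell bound of the cube shape",
              nrow(m), bound))
  }
  if (length(v)) dplyr::bind_rows(v) else .violation(character(), character())
}

#' Level labels per factor, in declared order
#'
#' @param cube A [data_cube()].
#' @return Named list of character vectors, one per factor.
#' @export
cube_factor_levels <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  out <- lapply(cube$factors$name, function(f) {
    cube$levels$label[cube$levels$factor_name == f]
  })
  stats::setNames(out, cube$factors$name)
}

# Canonical form used by cube_equal: component ordering is normalized so
# cubes built via different column/row orders compare equal.
canonicalize_cube <- function(cube) {
  cube$entities <- dplyr::arrange(cube$entities, .data$normalized_label)
  cube$levels <- dplyr::arrange(cube$levels,
                                match(.data$factor_name, cube$factors$name),
                                .data$label)
  cube$treatments <- dplyr::arrange(cube$treatments, .data$treatment_id)
  cube$qtypes <- dplyr::arrange(cube$qtypes, .data$input_label)
  cube$measurements <- dplyr::arrange(cube$measurements, .data$entity,
                                      .data$treatment_id, .data$qtype)
  cube
}

#' Compare two cubes up to canonical ordering
#'
#' @param a,b [data_cube()] objects.
#' @param tol Absolute tolerance on measurement values.
#' @return `TRUE` or `FALSE`.
#' @export
cube_equal <- function(a, b, tol = 1e-9) {
  a <- canonicalize_cube(a)
  b <- canonicalize_cube(b)
  same_tbl <- function(x, y, num_cols = character()) {
    if (!identical(dim(x), dim(y)) || !identical(names(x), names(y))) return(FALSE)
    for (cn in names(x)) {
      if (cn %in% num_cols) {
        xa <- x[[cn]]; ya <- y[[cn]]
        if (!identical(is.na(xa), is.na(ya))) return(FALSE)
        ok <- is.na(xa) | abs(xa - ya) <= tol
        if (!all(ok)) return(FALSE)
      } else {
        if (!identical(as.character(x[[cn]]), as.character(y[[cn]]))) return(FALSE)
      }
    }
    TRUE
  }
  identical(a$study_id, b$study_id) &&
    same_tbl(a$entities, b$entities) &&
    same_tbl(a$factors, b$factors) &&
    same_tbl(a$levels, b$levels) &&
    same_tbl(a$treatments, b$treatments) &&
    same_tbl(a$qtypes, b$qtypes) &&
    same_tbl(a$measurements, b$measurements, num_cols = "value")
}
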