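# Reading wide matrices and unpacking composed column headers.
#
# A header such as "R. chinensis 'Old Blush' sepals — average" is one cell of
# two crossed dimensions (treatment, quantitation type); the header grammar
# that decomposes it is configuration (a header_spec file), not code, so the
# same engine serves any matrix whose headers are regular.

#' Describe the delimited-text dialect of an input matrix
#'
#' @param delimiter Field separator (default `","`).
#' @param decimal_mark Decimal mark used in numeric cells; comma-decimal
#'   input must be declared here, it is never guessed.
#' @param quote Quote character.
#' @param row_label_col Index of the row-label column (default first).
#' @param missing_values Tokens read as missing measurement cells.
#' @return A `dialect` list.
#' @export
dialect <- function(delimiter = ",", decimal_mark = ".", quote = "\"",
                    row_label_col = 1L,
                    missing_values = c("", "nd", "n.d.", "tr", "NA")) {
  stopifnot(nchar(delimiter) == 1L, decimal_mark %in% c(".", ","))
  structure(list(delimiter = delimiter, decimal_mark = decimal_mark,
                 quote = quote, row_label_col = as.integer(row_label_col),
                 missing_values = missing_values),
            class = "dialect")
}

#' Read a wide-format matrix verbatim
#'
#' Returns the raw grid with no numeric coercion: row labels, normalized
#' column headers and a character value matrix. Structural defects (ragged
#' rows, duplicate headers after whitespace normalization) are errors that
#' name the offending line or header.
#'
#' @param path Delimited text file with one header row and one row-label
#'   column.
#' @param dialect A [dialect()].
#' @return A `raw_matrix` object.
#' @export
read_matrix <- function(path, dialect = fairomics::dialect()) {
  if (!file.exists(path)) stop("input matrix not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = dialect$delimiter,
                            quote = dialect$quote, comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])
    stop(sprintf("ragged input: line %d has %d fields where %d were expected (%s)",
                 bad[1], nf[bad[1]], nf[1], path), call. = FALSE)
  }
  df <- utils::read.table(path, header = FALSE, sep = dialect$delimiter,
                          quote = dialect$quote, colClasses = "character",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  headers <- normalize_header(as.character(df[1, ]))
  lab_col <- dialect$row_label_col
  data_headers <- headers[-lab_col]
  if (anyDuplicated(data_headers)) {
    dup <- unique(data_headers[duplicated(data_headers)])
    stop("duplicate column headers after normalization: ",
         paste0("'", dup, "'", collapse = ", "), call. = FALSE)
  }
  body <- df[-1, , drop = FALSE]
  values <- as.matrix(body[, -lab_col, drop = FALSE])
  dimnames(values) <- NULL
  m <- structure(
    list(row_labels = trimws(body[[lab_col]]),
         column_headers = data_headers,
         values = values,
         dialect = dialect),
    class = "raw_matrix")
  message(sprintf("read %d rows x %d data columns from %s",
                  length(m$row_labels), length(m$column_headers), path))
  m
}

#' Declare a header-decomposition grammar
#'
#' Rules are regular expressions with capture groups; `assign` names the
#' target of each group in order — a factor name, or `"qtype"` for the
#' quantitation-type slot. Rules are tried in order and exactly one may
#' match a header; captured tokens are normalized and passed through the
#' synonym table to canonical level / qtype labels.
#'
#' @param factors Factor names in declaration order.
#' @param rules List of lists, each with `pattern` (regex matched against
#'   the whole normalized header) and `assign` (character vector, one entry
#'   per capture group).
#' @param synonyms Named character vector alias -> canonical label
#'   (aliases compared after [normalize_label()]).
#' @param qtype_map Named character vector canonical qtype token ->
#'   canonical name (`sample_mean`, `standard_error_of_mean`); unmapped
#'   tokens become `other`.
#' @param default_qtype Label used when a rule captures no qtype slot.
#' @param case_insensitive Match rules case-insensitively (default).
#' @param unit Unit string stamped on every measurement (carried verbatim,
#'   never interpreted).
#' @param sample_size Sample size behind each summary statistic; the matrix
#'   itself does not carry it, so it enters here as configuration.
#' @param replicate_semantics `"technical"`, `"biological"` or
#'   `"unspecified"` — what the replicates were, hence what the SEM
#'   estimates.
#' @return A `header_spec` object.
#' @export
header_spec <- function(factors, rules, synonyms = character(),
                        qtype_map = c("average" = "sample_mean",
                                      "standard error" = "standard_error_of_mean"),
                        default_qtype = NULL, case_insensitive = TRUE,
                        unit = NA_character_, sample_size = NA_integer_,
                        replicate_semantics = "unspecified") {
  stopifnot(is.character(factors), length(factors) >= 1L)
  for (r in rules) {
    if (is.null(r$pattern) || is.null(r$assign)) {
      stop("each header rule needs 'pattern' and 'assign'", call. = FALSE)
    }
    unknown <- setdiff(r$assign, c(factors, "qtype"))
    if (length(unknown)) {
      stop("rule assigns to unknown target(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(r$assign)) {
      stop("rule assigns two capture groups to the same target", call. = FALSE)
    }
  }
  syn <- if (length(synonyms)) {
    stats::setNames(unname(unlist(synonyms)), normalize_label(names(synonyms)))
  } else stats::setNames(character(), character())
  qm <- if (length(qtype_map)) {
    stats::setNames(unname(unlist(qtype_map)), normalize_label(names(qtype_map)))
  } else stats::setNames(character(), character())
  structure(list(factors = factors, rules = rules, synonyms = syn,
                 qtype_map = qm, default_qtype = default_qtype,
                 case_insensitive = isTRUE(case_insensitive), unit = unit,
                 sample_size = as.integer(sample_size),
                 replicate_semantics = replicate_semantics),
            class = "header_spec")
}

#' Read a header spec from YAML
#' @param path File path.
#' @return A [header_spec()].
#' @export
read_header_spec <- function(path) {
  if (!file.exists(path)) stop("header spec not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  header_spec(
    factors = unlist(doc$factors),
    rules = lapply(doc$rules, function(r)
      list(pattern = r$pattern, assign = unlist(r$assign))),
    synonyms = unlist(doc$synonyms) %||% character(),
    qtype_map = unlist(doc$qtype_map) %||% character(),
    default_qtype = doc$default_qtype,
    case_insensitive = doc$case_insensitive %||% TRUE,
    unit = doc$unit %||% NA_character_,
    sample_size = doc$sample_size %||% NA_integer_,
    replicate_semantics = doc$replicate_semantics %||% "unspecified")
}

#' Write a header spec to YAML
#' @param spec A [header_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_header_spec <- function(spec, path) {
  stopifnot(inherits(spec, "header_spec"))
  doc <- list(factors = as.list(spec$factors),
              rules = lapply(spec$rules, function(r)
                list(pattern = r$pattern, assign = as.list(r$assign))),
              synonyms = as.list(spec$synonyms),
              qtype_map = as.list(spec$qtype_map),
              default_qtype = spec$default_qtype,
              case_insensitive = spec$case_insensitive,
              unit = spec$unit,
              sample_size = spec$sample_size,
              replicate_semantics = spec$replicate_semantics)
  yaml::write_yaml(doc, path)
  invisible(path)
}

.canonical_token <- function(token, spec) {
  key <- normalize_label(token)
  # quotes around tokens ('Old Blush') are decoration, not identity
  key <- trimws(gsub("^['\"]+|['\"]+$", "", key))
  if (key %in% names(spec$synonyms)) spec$synonyms[[key]] else key
}

.match_header <- function(header, spec) {
  hits <- list()
  for (i in seq_along(spec$rules)) {
    r <- spec$rules[[i]]
    pat <- stringr::regex(r$pattern, ignore_case = spec$case_insensitive)
    m <- stringr::str_match(header, pat)
    if (!is.na(m[1, 1])) hits[[length(hits) + 1L]] <- list(rule = i, groups = m[1, -1])
  }
  hits
}

#' Unpack composed column headers into a data cube
#'
#' Decomposes each data column into a treatment combination (one level per
#' factor) and a quantitation type, parses cell values numerically
#' (honouring the dialect's missing tokens and decimal mark), and assembles
#' a [data_cube()]. Level sets are the unions of levels seen per factor,
#' in first-appearance order; observed treatments are the distinct level
#' tuples across columns.
#'
#' In `strict` mode the first unmatched/ambiguous header or non-numeric
#' cell is an error; in `lenient` mode all findings are collected into a
#' report attached to the cube as attribute `"findings"` (offending cells
#' become missing).
#'
#' @param m A [read_matrix()] result.
#' @param spec A [header_spec()].
#' @param study_id Study identifier for the resulting cube.
#' @param mode `"strict"` or `"lenient"`.
#' @return A [data_cube()]; in lenient mode with a `findings` attribute
#'   (tibble of code, location, message).
#' @export
unpack_headers <- function(m, spec, study_id = "study",
                           mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "raw_matrix"), inherits(spec, "header_spec"))
  findings <- list()
  note <- function(code, location, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(code = code, location = location, message = message)
    if (mode == "strict") stop(message, call. = FALSE)
  }

  cols <- vector("list", length(m$column_headers))
  for (j in seq_along(m$column_headers)) {
    h <- m$column_headers[j]
    hits <- .match_header(h, spec)
    if (length(hits) == 0L) {
      note("UNMATCHED_HEADER", h,
           sprintf("header '%s' matched none of the %d rules", h,
                   length(spec$rules)))
      next
    }
    if (length(hits) > 1L) {
      note("AMBIGUOUS_HEADER", h,
           sprintf("header '%s' matched rules %s — at most one may match", h,
                   paste(vapply(hits, `[[`, 0L, "rule"), collapse = ", ")))
      next
    }
    rule <- spec$rules[[hits[[1]]$rule]]
    groups <- hits[[1]]$groups
    lv <- stats::setNames(rep(NA_character_, length(spec$factors)), spec$factors)
    qtype_label <- NULL
    for (g in seq_along(rule$assign)) {
      tok <- .canonical_token(groups[[g]], spec)
      if (rule$assign[g] == "qtype") qtype_label <- tok else lv[[rule$assign[g]]] <- tok
    }
    if (is.null(qtype_label)) {
      if (is.null(spec$default_qtype)) {
        note("NO_QTYPE", h,
             sprintf("header '%s': rule captures no quantitation type and no default_qtype is set", h))
        next
      }
      qtype_label <- spec$default_qtype
    }
    used <- !is.na(lv)
    cols[[j]] <- list(col = j, levels = lv[used], qtype = qtype_label)
  }
  cols <- cols[!vapply(cols, is.null, TRUE)]

  # factor level sets, first-appearance order over columns
  lev_rows <- list()
  for (f in spec$factors) {
    seen <- character()
    for (cc in cols) if (f %in% names(cc$levels) && !cc$levels[[f]] %in% seen) {
      seen <- c(seen, cc$levels[[f]])
    }
    if (length(seen)) {
      lev_rows[[f]] <- tibble::tibble(factor_name = f, label = seen)
    }
  }
  levels_tbl <- if (length(lev_rows)) dplyr::bind_rows(lev_rows) else
    tibble::tibble(factor_name = character(), label = character())
  used_factors <- unique(levels_tbl$factor_name)
  factors_tbl <- tibble::tibble(name = spec$factors[spec$factors %in% used_factors])

  # observed treatments in first-appearance order
  trt_rows <- list()
  col_map <- tibble::tibble(header = character(), treatment_id = character(),
                            qtype = character(), col = integer())
  for (cc in cols) {
    ordered_levels <- cc$levels[factors_tbl$name]
    tid <- paste(ordered_levels, collapse = " | ")
    if (!tid %in% names(trt_rows)) {
      row <- c(list(treatment_id = tid, status = "observed"),
               as.list(ordered_levels))
      trt_rows[[tid]] <- tibble::as_tibble(row)
    }
    key <- paste(tid, cc$qtype, sep = "\r")
    if (key %in% paste(col_map$treatment_id, col_map$qtype, sep = "\r")) {
      note("DUPLICATE_COLUMN", m$column_headers[cc$col],
           sprintf("column '%s' duplicates the (treatment, qtype) pair of an earlier column",
                   m$column_headers[cc$col]))
      next
    }
    col_map <- dplyr::bind_rows(col_map, tibble::tibble(
      header = m$column_headers[cc$col], treatment_id = tid,
      qtype = cc$qtype, col = cc$col))
  }
  treatments <- dplyr::bind_rows(trt_rows)

  qtypes_seen <- unique(col_map$qtype)
  canon <- function(q) {
    key <- normalize_label(q)
    if (key %in% names(spec$qtype_map)) spec$qtype_map[[key]] else "other"
  }
  qtypes <- tibble::tibble(
    input_label = qtypes_seen,
    canonical_name = unname(vapply(qtypes_seen, canon, "")))
  qtypes$requires_sample_size <-
    qtypes$canonical_name %in% c("sample_mean", "standard_error_of_mean")

  # cell values
  entities <- entity_table(tibble::tibble(input_label = m$row_labels))
  dial <- m$dialect
  parse_cell <- function(x) {
    x <- trimws(x)
    if (x %in% dial$missing_values || is.na(x)) return(NA_real_)
    if (dial$decimal_mark == ",") x <- gsub(",", ".", gsub("\\.", "", x))
    suppressWarnings(as.numeric(x))
  }
  meas <- vector("list", nrow(col_map))
  for (k in seq_len(nrow(col_map))) {
    j <- col_map$col[k]
    raw <- m$values[, j]
    vals <- vapply(raw, parse_cell, 0, USE.NAMES = FALSE)
    bad <- which(is.na(vals) & !trimws(raw) %in% dial$missing_values & !is.na(raw))
    for (b in bad) {
      note("NON_NUMERIC_CELL", sprintf("row %d, column '%s'", b, col_map$header[k]),
           sprintf("cell at data row %d, column '%s' is neither numeric nor a declared missing token: '%s'",
                   b, col_map$header[k], raw[b]))
    }
    qt <- qtypes[qtypes$input_label == col_map$qtype[k], ]
    meas[[k]] <- tibble::tibble(
      entity = entities$normalized_label,
      treatment_id = col_map$treatment_id[k],
      qtype = col_map$qtype[k],
      value = vals,
      unit = spec$unit,
      sample_size = if (qt$requires_sample_size) spec$sample_size else NA_integer_,
      replicate_semantics = spec$replicate_semantics)
  }
  measurements <- dplyr::bind_rows(meas)

  cube <- data_cube(study_id = study_id, entities = entities,
                    factors = factors_tbl, levels = levels_tbl,
                    treatments = treatments, qtypes = qtypes,
                    measurements = measurements,
                    provenance = sprintf("unpacked from %d composed column headers",
                                         length(m$column_headers)))
  attr(cube, "column_map") <- col_map[, c("header", "treatment_id", "qtype")]
  if (mode == "lenient") {
    attr(cube, "findings") <- if (length(findings)) dplyr::bind_rows(findings) else
      tibble::tibble(code = character(), location = character(), message = character())
  }
  cube
}

#' Flatten a cube into tidy records
#'
#' One record per measurement: entity label, one column per factor, the
#' quantitation type, value, unit and sample size. Ordering is
#' deterministic — cube entity order, then treatment order, then qtype
#' order — and the mapping is lossless: regrouping the records rebuilds an
#' identical cube.
#'
#' @param cube A [data_cube()].
#' @return A tibble.
#' @export
tidy_table <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  m <- cube$measurements
  fac_cols <- cube$factors$name
  trt <- cube$treatments[, c("treatment_id", fac_cols), drop = FALSE]
  out <- dplyr::left_join(m, trt, by = "treatment_id")
  out$entity <- factor(out$entity, levels = cube$entities$normalized_label)
  out$treatment_id <- factor(out$treatment_id,
                             levels = cube$treatments$treatment_id)
  out$qtype <- factor(out$qtype, levels = cube$qtypes$input_label)
  out <- dplyr::arrange(out, .data$entity, .data$treatment_id, .data$qtype)
  out$entity <- as.character(out$entity)
  out$treatment_id <- as.character(out$treatment_id)
  out$qtype <- as.character(out$qtype)
  out[, c("entity", fac_cols, "qtype", "value", "unit", "sample_size"),
      drop = FALSE]
}
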