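# Label normalization and offline ontology-term resolution.
#
# Free-text compound / cultivar / anatomy / statistic labels are mapped to
# terms through local term-map files only; there is no network access and no
# fuzzy matching — an unmatched label stays unresolved, never guessed.

# Greek transliteration applied before matching; fixed, not configurable.
.greek_table <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta", "θ" = "theta", "ι" = "iota",
  "κ" = "kappa", "λ" = "lambda", "μ" = "mu",
  "ν" = "nu", "ξ" = "xi", "π" = "pi", "ρ" = "rho",
  "σ" = "sigma", "τ" = "tau", "φ" = "phi",
  "χ" = "chi", "ψ" = "psi", "ω" = "omega")

# typographic quote / dash / sign variants mapped to ASCII
.typo_table <- c(
  "‘" = "'", "’" = "'", "‛" = "'",
  "“" = "\"", "”" = "\"",
  "‐" = "-", "‑" = "-", "‒" = "-", "–" = "-",
  "—" = "-", "―" = "-", "−" = "-",
  " " = " ")

.ascii_fold <- function(x) {
  for (i in seq_along(.typo_table)) {
    x <- gsub(names(.typo_table)[i], .typo_table[[i]], x, fixed = TRUE)
  }
  x
}

#' Normalize a free-text label
#'
#' Case-folds, trims, collapses internal whitespace, maps typographic quotes
#' and dashes to ASCII and transliterates Greek letters (beta-ionone from
#' its Greek-letter spelling, and so on). Deterministic and idempotent; used
#' as the join key for all term resolution.
#'
#' @param label Character vector.
#' @return Character vector of normalized labels.
#' @export
normalize_label <- function(label) {
  x <- .ascii_fold(label)
  for (i in seq_along(.greek_table)) {
    x <- gsub(names(.greek_table)[i], .greek_table[[i]], x, fixed = TRUE)
  }
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Header normalization is lighter: whitespace + typography only, case kept
# (rule matching is case-insensitive instead, so captured tokens retain
# their source casing until synonym lookup).
normalize_header <- function(x) {
  trimws(gsub("\\s+", " ", .ascii_fold(x)))
}

.term_domains <- c("chemical", "taxon", "anatomy", "statistic")

#' Construct a term map
#'
#' An offline label -> ontology-term dictionary for one annotation domain.
#' Entry keys and synonym aliases are stored normalized (see
#' [normalize_label()]); an alias mapping to more than one entry is an
#' ambiguity and is rejected at construction time.
#'
#' @param domain One of `"chemical"`, `"taxon"`, `"anatomy"`, `"statistic"`.
#' @param entries Named list: normalized label -> list with `curie`,
#'   optional `iri`, `label` (term label) and, for the chemical domain,
#'   `inchi`. An entry may instead carry `candidates`, a list of such
#'   records, in which case the label resolves as ambiguous.
#' @param synonyms Named character vector: alias -> entry label.
#' @param ontology,version Metadata strings carried through to reports.
#' @return A `term_map` object.
#' @export
term_map <- function(domain, entries = list(), synonyms = character(),
                     ontology = NA_character_, version = NA_character_) {
  domain <- match.arg(domain, .term_domains)
  names(entries) <- normalize_label(names(entries) %||% character())
  if (anyDuplicated(names(entries))) {
    stop("ambiguous term map: duplicate entry labels after normalization: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "),
         call. = FALSE)
  }
  if (length(synonyms)) {
    syn_alias <- normalize_label(names(synonyms))
    syn_target <- normalize_label(unname(unlist(synonyms)))
    if (anyDuplicated(syn_alias)) {
      clash <- unique(syn_alias[duplicated(syn_alias)])
      stop("ambiguous term map: alias maps to more than one entry: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(syn_target, names(entries))
    if (length(missing)) {
      stop("term map synonyms point at unknown entries: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    synonyms <- stats::setNames(syn_target, syn_alias)
  } else {
    synonyms <- stats::setNames(character(), character())
  }
  structure(list(domain = domain, entries = entries, synonyms = synonyms,
                 ontology = ontology, version = version),
            class = "term_map")
}

#' Read a term map from a YAML file
#'
#' Expected layout: top-level `domain`, `ontology`, `version`, `entries`
#' (label -> {curie, iri, label, inchi}), `synonyms` (alias -> label).
#'
#' @param path File path.
#' @return A [term_map()].
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop("term map file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  term_map(domain = doc$domain,
           entries = doc$entries %||% list(),
           synonyms = unlist(doc$synonyms) %||% character(),
           ontology = doc$ontology %||% NA_character_,
           version = doc$version %||% NA_character_)
}

#' Write a term map to YAML
#' @param map A [term_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(map, path) {
  stopifnot(inherits(map, "term_map"))
  doc <- list(domain = map$domain, ontology = map$ontology,
              version = map$version, entries = map$entries,
              synonyms = as.list(map$synonyms))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Resolve one label against a term map
#'
#' Exact match on the normalized label first, then the synonym table.
#' Absence is a status, not an error, and no fuzzy matching is attempted.
#'
#' @param label A single label string.
#' @param map A [term_map()].
#' @return List with `status` (`"resolved"`, `"ambiguous"`, `"unresolved"`),
#'   `term` (list with `curie`, `iri`, `label`, or `NULL`), `inchi`
#'   (or `NA`), and `candidates` (list, non-empty only when ambiguous).
#' @export
resolve_label <- function(label, map) {
  stopifnot(inherits(map, "term_map"))
  key <- normalize_label(label)
  if (!key %in% names(map$entries) && key %in% names(map$synonyms)) {
    key <- map$synonyms[[key]]
  }
  entry <- map$entries[[key]]
  if (is.null(entry)) {
    return(list(status = "unresolved", term = NULL, inchi = NA_character_,
                candidates = list()))
  }
  if (!is.null(entry$candidates)) {
    return(list(status = "ambiguous", term = NULL, inchi = NA_character_,
                candidates = entry$candidates))
  }
  term <- list(curie = entry$curie,
               iri = entry$iri %||% curie_to_iri(entry$curie),
               label = entry$label %||% key)
  list(status = "resolved", term = term,
       inchi = entry$inchi %||% NA_character_, candidates = list())
}

.resolve_many <- function(labels, map) {
  res <- lapply(labels, resolve_label, map = map)
  tibble::tibble(
    label = labels,
    status = vapply(res, `[[`, "", "status"),
    curie = vapply(res, function(r) r$term$curie %||% NA_character_, ""),
    iri = vapply(res, function(r) r$term$iri %||% NA_character_, ""),
    term_label = vapply(res, function(r) r$term$label %||% NA_character_, ""),
    inchi = vapply(res, function(r) r$inchi %||% NA_character_, ""))
}

#' Annotate a cube with ontology terms
#'
#' Routes each annotatable label set through its domain's term map:
#' molecular entities through `chemical`, factor levels through the map
#' named by `routing` for their factor, quantitation types through
#' `statistic`. Original labels are always preserved; annotation attaches
#' terms only and is idempotent.
#'
#' @param cube A [data_cube()].
#' @param maps Named list of [term_map()]s keyed by domain.
#' @param routing Named character vector factor name -> domain (e.g.
#'   `c("rose cultivar" = "taxon", "organism part" = "anatomy")`).
#' @param mode `"strict"` errors when an annotatable factor has no routing
#'   entry; `"lenient"` warns and leaves it unannotated.
#' @return List with `cube` (annotated) and `report` (an
#'   `annotation_report`: tibble of label, domain, status plus a counts
#'   summary attribute).
#' @export
annotate_cube <- function(cube, maps, routing = character(),
                          mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cube, "data_cube"))
  if (inherits(maps, "term_map")) maps <- list(maps)
  names(maps) <- vapply(maps, `[[`, "", "domain")
  rows <- list()
  add_rows <- function(domain, res) {
    rows[[length(rows) + 1L]] <<-
      tibble::tibble(domain = domain, label = res$label, status = res$status)
  }
  if ("chemical" %in% names(maps) && nrow(cube$entities)) {
    res <- .resolve_many(cube$entities$normalized_label, maps$chemical)
    cube$entities$curie <- res$curie
    cube$entities$iri <- res$iri
    cube$entities$term_label <- res$term_label
    cube$entities$inchi <- res$inchi
    cube$entities$resolution <- res$status
    add_rows("chemical", res)
  }
  for (f in cube$factors$name) {
    dom <- if (f %in% names(routing)) routing[[f]] else NA_character_
    if (is.na(dom)) {
      if (length(maps[setdiff(names(maps), "chemical")])) {
        msg <- paste0("no term-map domain routed for factor '", f, "'")
        if (mode == "strict" && any(c("taxon", "anatomy") %in% names(maps))) {
          stop(msg, call. = FALSE)
        }
      }
      next
    }
    if (!dom %in% names(maps)) {
      msg <- paste0("factor '", f, "' routed to domain '", dom,
                    "' but no such term map was supplied")
      if (mode == "strict") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      next
    }
    idx <- cube$levels$factor_name == f
    res <- .resolve_many(cube$levels$label[idx], maps[[dom]])
    cube$levels$curie[idx] <- res$curie
    cube$levels$iri[idx] <- res$iri
    cube$levels$term_label[idx] <- res$term_label
    add_rows(dom, res)
  }
  if ("statistic" %in% names(maps) && nrow(cube$qtypes)) {
    res <- .resolve_many(cube$qtypes$input_label, maps$statistic)
    cube$qtypes$curie <- res$curie
    cube$qtypes$iri <- res$iri
    cube$qtypes$term_label <- res$term_label
    add_rows("statistic", res)
  }
  detail <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(domain = character(), label = character(), status = character())
  detail <- dplyr::distinct(detail)
  report <- structure(detail, class = c("annotation_report", class(detail)))
  list(cube = cube, report = report)
}

#' Summarise an annotation report
#'
#' @param report The report component of [annotate_cube()]'s result.
#' @return Tibble with per-domain counts of resolved / ambiguous /
#'   unresolved labels; counts partition the distinct labels submitted.
#' @export
annotation_summary <- function(report) {
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(report), .data$domain),
    n_labels = dplyr::n(),
    resolved = sum(.data$status == "resolved"),
    ambiguous = sum(.data$status == "ambiguous"),
    unresolved = sum(.data$status == "unresolved"),
    .groups = "drop")
  dplyr::arrange(out, .data$domain)
}

#' @export
print.annotation_report <- function(x, ...) {
  s <- annotation_summary(x)
  cat("<annotation_report>\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %d labels: %d resolved, %d ambiguous, %d unresolved\n",
                s$domain[i], s$n_labels[i], s$resolved[i], s$ambiguous[i],
                s$unresolved[i]))
  }
  invisible(x)
}
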