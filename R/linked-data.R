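# RDF conversion of an annotated cube + design model.
#
# The graph is held as a tibble of (subject, predicate, object, object_kind,
# datatype) rows; subjects and predicates are absolute IRIs, objects are
# IRIs or typed literals. Instance IRIs are minted deterministically from
# the study id and the node's identifying labels, so rebuilding the graph
# from the same inputs yields an IRI-identical statement set — no blank
# nodes anywhere. Queries are implemented as graph traversals whose answers
# are contractually equal to those computed from the in-memory model;
# equivalent SPARQL text ships under inst/queries/.

.rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
.rdfs_label <- "http://www.w3.org/2000/01/rdf-schema#label"
.xsd <- function(x) paste0("http://www.w3.org/2001/XMLSchema#", x)

#' Default vocabulary map for graph building
#'
#' Maps every model concept the graph builder uses to an ontology term
#' (CURIE + IRI). Accessions are configuration, not logic: swap in your
#' own map (same concept keys) to retarget the graph to other releases or
#' ontologies. Defaults use OBO-style CURIEs for the statistics / ontology
#' concepts the model needs (study design, independent variable, factor
#' level, sample mean, standard error of the mean, sample size, ...).
#'
#' @param base_iri Stem for minted instance IRIs.
#' @return A `vocabulary_map` list with `concepts`, `prefixes`, `base_iri`.
#' @export
default_vocabulary <- function(base_iri = "https://w3id.org/fairomics/") {
  cc <- function(curie, label) list(curie = curie, label = label,
                                    iri = curie_to_iri(curie))
  structure(list(
    base_iri = base_iri,
    prefixes = c(obo = "http://purl.obolibrary.org/obo/"),
    concepts = list(
      study = cc("OBI:0000066", "investigation"),
      study_design = cc("OBI:0500000", "study design"),
      single_factor = cc("STATO:0000270", "single factor study design"),
      full_factorial = cc("STATO:0000270", "full factorial design"),
      fractional_factorial = cc("STATO:0000298", "fractional factorial design"),
      independent_variable = cc("STATO:0000087", "independent variable"),
      factor_level = cc("STATO:0000861", "factor level"),
      treatment = cc("OBI:0000181", "treatment"),
      measurement_datum = cc("IAO:0000109", "measurement datum"),
      sample_mean = cc("STATO:0000401", "sample mean"),
      standard_error_of_mean = cc("STATO:0000037", "standard error of the mean"),
      other_statistic = cc("STATO:0000039", "statistic"),
      sample_size = cc("STATO:0000088", "sample size"),
      molecular_entity = cc("CHEBI:23367", "molecular entity"),
      has_design = cc("STATO:0000002", "has study design"),
      has_independent_variable = cc("STATO:0000003", "has independent variable"),
      has_level = cc("STATO:0000004", "has factor level"),
      member_of_variable = cc("STATO:0000005", "is level of variable"),
      has_factor_level = cc("STATO:0000006", "treatment has factor level"),
      is_about = cc("IAO:0000136", "is about"),
      has_treatment = cc("STATO:0000007", "computed over treatment"),
      has_quantitation_type = cc("STATO:0000008", "has quantitation type"),
      has_value = cc("STATO:0000129", "has value"),
      has_unit = cc("IAO:0000039", "has measurement unit label"),
      has_sample_size = cc("STATO:0000089", "computed over sample size"),
      has_inchi = cc("CHEBI:0000001", "has InChI"),
      has_order = cc("IAO:0000614", "has ordinal position"))),
    class = "vocabulary_map")
}

#' Read a vocabulary map from YAML
#' @param path File path; layout mirrors [default_vocabulary()].
#' @return A `vocabulary_map`.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  concepts <- lapply(doc$concepts, function(x) {
    list(curie = x$curie, label = x$label,
         iri = x$iri %||% curie_to_iri(x$curie))
  })
  structure(list(base_iri = doc$base_iri %||% "https://w3id.org/fairomics/",
                 prefixes = unlist(doc$prefixes) %||%
                   c(obo = "http://purl.obolibrary.org/obo/"),
                 concepts = concepts),
            class = "vocabulary_map")
}

.vocab_iri <- function(vocab, concept) {
  entry <- vocab$concepts[[concept]]
  if (is.null(entry)) {
    stop("vocabulary map lacks an entry for concept '", concept, "'",
         call. = FALSE)
  }
  entry$iri
}

# IRI-safe slug: lowercase, non-alphanumerics collapsed to single hyphens.
.slug <- function(x) {
  x <- gsub("[^a-z0-9]+", "-", tolower(x))
  gsub("^-|-$", "", x)
}

.triple <- function(s, p, o, kind = "iri", datatype = NA_character_) {
  tibble::tibble(subject = s, predicate = p, object = o,
                 object_kind = kind, datatype = datatype)
}

empty_graph <- function() {
  g <- .triple(character(), character(), character(), character(), character())
  structure(g, class = c("triple_graph", class(g)))
}

.as_graph <- function(tbl) {
  tbl <- dplyr::distinct(tibble::as_tibble(tbl))
  structure(tbl, class = c("triple_graph", setdiff(class(tbl), "triple_graph")))
}

#' Convert an annotated cube and its design model to an RDF graph
#'
#' Emits one study node, one design node typed by the design
#' classification, one node per independent variable linked to its level
#' nodes, one node per observed treatment linked to its constituent
#' levels, and one measurement-datum node per measurement carrying exactly
#' one entity link, one treatment link, one quantitation-type link, the
#' numeric value, the unit, and (for quantitation types that require it)
#' the sample size. Resolved entities get CURIE-derived IRIs and InChI
#' literals; unresolved ones get minted IRIs.
#'
#' @param cube An annotated [data_cube()].
#' @param design The matching [infer_design()] model.
#' @param vocab A vocabulary map; see [default_vocabulary()].
#' @return A `triple_graph` tibble.
#' @export
build_graph <- function(cube, design, vocab = default_vocabulary()) {
  stopifnot(inherits(cube, "data_cube"), inherits(design, "design_model"))
  V <- function(concept) .vocab_iri(vocab, concept)
  base <- paste0(vocab$base_iri, "study/", .slug(cube$study_id))
  tr <- list()
  add <- function(s, p, o, kind = "iri", datatype = NA_character_) {
    tr[[length(tr) + 1L]] <<- .triple(s, p, o, kind, datatype)
  }
  lit <- function(s, p, o, dt = NULL) add(s, p, as.character(o), "literal",
                                          if (is.null(dt)) NA_character_ else dt)

  study_iri <- base
  design_iri <- paste0(base, "/design")
  add(study_iri, .rdf_type, V("study"))
  lit(study_iri, .rdfs_label, cube$study_id)
  add(study_iri, V("has_design"), design_iri)
  add(design_iri, .rdf_type, V(design$classification))
  lit(design_iri, .rdfs_label,
      paste(gsub("_", " ", design$classification), "of study", cube$study_id))

  level_iri <- function(f, l) paste0(base, "/level/", .slug(f), "/", .slug(l))
  var_iris <- character()
  for (i in seq_len(nrow(design$factors))) {
    f <- design$factors$name[i]
    vi <- paste0(base, "/variable/", .slug(f))
    var_iris[[f]] <- vi
    add(design_iri, V("has_independent_variable"), vi)
    add(vi, .rdf_type, V("independent_variable"))
    lit(vi, .rdfs_label, f)
    lit(vi, V("has_order"), i, .xsd("integer"))
    lv <- design$levels[design$levels$factor_name == f, , drop = FALSE]
    for (k in seq_len(nrow(lv))) {
      li <- level_iri(f, lv$label[k])
      add(vi, V("has_level"), li)
      add(li, .rdf_type, V("factor_level"))
      if (!is.na(lv$iri[k])) add(li, .rdf_type, lv$iri[k])
      lit(li, .rdfs_label, lv$label[k])
      lit(li, V("has_order"), k, .xsd("integer"))
      add(li, V("member_of_variable"), vi)
    }
  }

  trt_iri <- stats::setNames(
    paste0(base, "/treatment/", vapply(cube$treatments$treatment_id, .slug, "")),
    cube$treatments$treatment_id)
  obs <- cube$treatments[cube$treatments$status == "observed", , drop = FALSE]
  for (i in seq_len(nrow(obs))) {
    ti <- trt_iri[[obs$treatment_id[i]]]
    add(ti, .rdf_type, V("treatment"))
    lit(ti, .rdfs_label, obs$treatment_id[i])
    for (f in design$factors$name) {
      add(ti, V("has_factor_level"), level_iri(f, obs[[f]][i]))
    }
  }

  ent <- cube$entities
  ent_iri <- ifelse(!is.na(ent$iri), ent$iri,
                    ifelse(!is.na(ent$curie),
                           vapply(ent$curie, curie_to_iri, ""),
                           paste0(base, "/entity/", vapply(ent$normalized_label, .slug, ""))))
  names(ent_iri) <- ent$normalized_label
  for (i in seq_len(nrow(ent))) {
    add(ent_iri[i], .rdf_type, V("molecular_entity"))
    lit(ent_iri[i], .rdfs_label, ent$input_label[i])
    if (!is.na(ent$inchi[i])) lit(ent_iri[i], V("has_inchi"), ent$inchi[i])
  }

  qt <- cube$qtypes
  qt_iri <- character(nrow(qt))
  for (i in seq_len(nrow(qt))) {
    qt_iri[i] <- if (!is.na(qt$iri[i])) {
      qt$iri[i]
    } else if (qt$canonical_name[i] %in% c("sample_mean", "standard_error_of_mean")) {
      V(qt$canonical_name[i])
    } else {
      paste0(base, "/qtype/", .slug(qt$input_label[i]))
    }
    add(qt_iri[i], .rdf_type, V(
      if (qt$canonical_name[i] %in% c("sample_mean", "standard_error_of_mean"))
        qt$canonical_name[i] else "other_statistic"))
    lit(qt_iri[i], .rdfs_label, qt$input_label[i])
  }
  names(qt_iri) <- qt$input_label
  req_n <- stats::setNames(qt$requires_sample_size, qt$input_label)

  m <- cube$measurements
  for (i in seq_len(nrow(m))) {
    mi <- paste0(base, "/measurement/", .slug(m$entity[i]), "--",
                 .slug(m$treatment_id[i]), "--", .slug(m$qtype[i]))
    add(mi, .rdf_type, V("measurement_datum"))
    add(mi, V("is_about"), ent_iri[[m$entity[i]]])
    add(mi, V("has_treatment"), trt_iri[[m$treatment_id[i]]])
    add(mi, V("has_quantitation_type"), qt_iri[[m$qtype[i]]])
    if (!is.na(m$value[i])) {
      lit(mi, V("has_value"), trimws(formatC(m$value[i], digits = 15, format = "g")),
          .xsd("double"))
    }
    if (!is.na(m$unit[i])) lit(mi, V("has_unit"), m$unit[i])
    if (req_n[[m$qtype[i]]] && !is.na(m$sample_size[i])) {
      lit(mi, V("has_sample_size"), m$sample_size[i], .xsd("integer"))
    }
  }
  .as_graph(dplyr::bind_rows(tr))
}

.nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

.nt_object <- function(g) {
  ifelse(g$object_kind == "iri", paste0("<", g$object, ">"),
         paste0("\"", .nt_escape(g$object), "\"",
                ifelse(is.na(g$datatype), "", paste0("^^<", g$datatype, ">"))))
}

#' Serialize a triple graph
#'
#' N-Triples output is canonically sorted by (subject, predicate, object)
#' so identical graphs give byte-identical files; Turtle output groups
#' statements by subject under `@prefix` declarations.
#'
#' @param g A `triple_graph`.
#' @param path Output file.
#' @param format `"ntriples"` or `"turtle"`.
#' @return `path`, invisibly.
#' @export
serialize_graph <- function(g, path, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "triple_graph"))
  g <- dplyr::arrange(dplyr::distinct(tibble::as_tibble(g)),
                      .data$subject, .data$predicate, .data$object)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "ntriples") {
    if (nrow(g)) {
      writeLines(paste0("<", g$subject, "> <", g$predicate, "> ",
                        .nt_object(g), " ."), con, sep = "\n")
    }
    return(invisible(path))
  }
  prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                rdfs = "http://www.w3.org/2000/01/rdf-schema#",
                xsd = "http://www.w3.org/2001/XMLSchema#",
                obo = "http://purl.obolibrary.org/obo/")
  compact <- function(iri) {
    for (p in names(prefixes)) {
      stem <- prefixes[[p]]
      hit <- startsWith(iri, stem)
      local <- substring(iri, nchar(stem) + 1L)
      ok <- hit & grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local) & !grepl("\\.$", local)
      iri <- ifelse(ok, paste0(p, ":", local), iri)
    }
    ifelse(grepl("^[a-z]+:[^/]", iri) & !grepl("^https?:", iri), iri,
           paste0("<", iri, ">"))
  }
  lines <- paste0("@prefix ", names(prefixes), ": <", prefixes, "> .")
  obj <- ifelse(g$object_kind == "iri", compact(g$object),
                paste0("\"", .nt_escape(g$object), "\"",
                       ifelse(is.na(g$datatype), "",
                              paste0("^^", compact(g$datatype)))))
  pred <- compact(g$predicate)
  pred[g$predicate == .rdf_type] <- "a"
  for (s in unique(g$subject)) {
    idx <- which(g$subject == s)
    body <- paste0("    ", pred[idx], " ", obj[idx],
                   c(rep(" ;", length(idx) - 1L), " ."))
    lines <- c(lines, "", paste0("<", s, ">"), body)
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an N-Triples file into a triple graph
#'
#' Minimal reader for the subset this package writes (IRI subjects and
#' predicates; IRI or typed-literal objects). Used for round-trip checks
#' and by the query front-end.
#'
#' @param path N-Triples file.
#' @return A `triple_graph`.
#' @export
read_ntriples <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_graph())
  m <- stringr::str_match(
    lines,
    "^<([^>]*)>\\s+<([^>]*)>\\s+(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>)?)\\s*\\.\\s*$")
  bad <- which(is.na(m[, 1]))
  if (length(bad)) {
    stop("unparseable N-Triples line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  }
  unescape <- function(x) {
    x <- gsub("\\n", "\n", x, fixed = TRUE)
    x <- gsub("\\r", "\r", x, fixed = TRUE)
    x <- gsub("\\\"", "\"", x, fixed = TRUE)
    gsub("\\\\", "\\", x, fixed = TRUE)
  }
  is_iri <- !is.na(m[, 4])
  .as_graph(tibble::tibble(
    subject = m[, 2], predicate = m[, 3],
    object = ifelse(is_iri, m[, 4], unescape(m[, 5])),
    object_kind = ifelse(is_iri, "iri", "literal"),
    datatype = m[, 6]))
}

.g_objects <- function(g, s = NULL, p = NULL) {
  idx <- rep(TRUE, nrow(g))
  if (!is.null(s)) idx <- idx & g$subject %in% s
  if (!is.null(p)) idx <- idx & g$predicate %in% p
  g$object[idx]
}

.g_label <- function(g, s) {
  out <- g$object[g$subject == s & g$predicate == .rdfs_label]
  if (length(out)) out[1] else NA_character_
}

.g_order <- function(g, s, vocab) {
  o <- g$object[g$subject == s & g$predicate == .vocab_iri(vocab, "has_order")]
  if (length(o)) as.integer(o[1]) else NA_integer_
}

#' Query: study predictor variables and their levels
#'
#' The graph-side answer to "retrieve study predictor variables and their
#' levels"; contractually equal to [cube_factor_levels()] /
#' [infer_design()] on the in-memory model.
#'
#' @param g A `triple_graph` built by [build_graph()] (or re-read from
#'   N-Triples).
#' @param vocab The vocabulary map the graph was built with.
#' @return Named list: variable name -> ordered character vector of level
#'   labels. Empty (with a warning) when the graph has no design node.
#' @export
query_predictors <- function(g, vocab = default_vocabulary()) {
  stopifnot(inherits(g, "triple_graph"))
  p_var <- .vocab_iri(vocab, "has_independent_variable")
  vars <- unique(.g_objects(g, p = p_var))
  if (!length(vars)) {
    warning("graph contains no design node; no predictor variables found")
    return(stats::setNames(list(), character()))
  }
  ord <- vapply(vars, function(v) .g_order(g, v, vocab), 0L)
  vars <- vars[order(ord)]
  p_lev <- .vocab_iri(vocab, "has_level")
  out <- lapply(vars, function(v) {
    levs <- unique(.g_objects(g, s = v, p = p_lev))
    lev_ord <- vapply(levs, function(l) .g_order(g, l, vocab), 0L)
    unname(vapply(levs[order(lev_ord)], function(l) .g_label(g, l), ""))
  })
  stats::setNames(out, unname(vapply(vars, function(v) .g_label(g, v), "")))
}

#' Query: sample size behind a summary statistic
#'
#' The graph-side answer to "what is the sample size used to compute the
#' mean?". Selects measurement-datum nodes by treatment label and
#' quantitation type and returns their sample-size literal.
#'
#' @param g A `triple_graph`.
#' @param treatment Treatment label (the `" | "`-joined level tuple), or
#'   `NULL` for any treatment.
#' @param qtype Canonical quantitation-type name (`"sample_mean"`,
#'   `"standard_error_of_mean"`) or a qtype label present in the graph.
#' @param vocab The vocabulary map.
#' @return Integer sample size, or `NA` (with a warning) when nothing
#'   matches or the qtype carries no sample size.
#' @export
query_sample_size <- function(g, treatment = NULL, qtype = "sample_mean",
                              vocab = default_vocabulary()) {
  stopifnot(inherits(g, "triple_graph"))
  p_trt <- .vocab_iri(vocab, "has_treatment")
  p_qt <- .vocab_iri(vocab, "has_quantitation_type")
  p_n <- .vocab_iri(vocab, "has_sample_size")
  qt_iris <- if (qtype %in% names(vocab$concepts)) {
    # the concept IRI itself, plus any qtype node typed by it
    v <- .vocab_iri(vocab, qtype)
    unique(c(v, g$subject[g$predicate == .rdf_type & g$object == v]))
  } else {
    labs <- g$subject[g$predicate == .rdfs_label & g$object == qtype]
    unique(labs)
  }
  meas <- unique(g$subject[g$predicate == p_qt & g$object %in% qt_iris])
  if (!is.null(treatment)) {
    trt_nodes <- g$subject[g$predicate == .rdfs_label & g$object == treatment]
    trt_nodes <- unique(trt_nodes[trt_nodes %in%
                                    g$object[g$predicate == p_trt]])
    if (!length(trt_nodes)) {
      warning("no treatment in the graph matches '", treatment, "'")
      return(NA_integer_)
    }
    meas <- meas[meas %in% g$subject[g$predicate == p_trt &
                                       g$object %in% trt_nodes]]
  }
  n <- unique(as.integer(g$object[g$subject %in% meas & g$predicate == p_n]))
  if (!length(n)) {
    warning("no sample-size literal found for the selected measurements")
    return(NA_integer_)
  }
  if (length(n) > 1L) {
    warning("mixed sample sizes across selected measurements; returning all")
    return(sort(n))
  }
  n
}

#' Export a plot-ready table from the graph
#'
#' Joins the sample-mean and SEM measurement data per (entity, treatment)
#' into flat records suitable for bar/point plots with error bars.
#'
#' @param g A `triple_graph` holding both quantitation types.
#' @param treatments Character vector of treatment labels to keep
#'   (`NULL` = all).
#' @param vocab The vocabulary map.
#' @return Tibble with `entity`, one column per independent variable,
#'   `mean`, `sem`, `unit`.
#' @export
export_plot_table <- function(g, treatments = NULL,
                              vocab = default_vocabulary()) {
  stopifnot(inherits(g, "triple_graph"))
  V <- function(x) .vocab_iri(vocab, x)
  meas <- g$subject[g$predicate == .rdf_type & g$object == V("measurement_datum")]
  if (!length(meas)) {
    return(tibble::tibble(entity = character(), mean = double(),
                          sem = double(), unit = character()))
  }
  one <- function(s, p) {
    o <- g$object[g$subject == s & g$predicate == p]
    if (length(o)) o[1] else NA_character_
  }
  rec <- tibble::tibble(
    node = unique(meas),
    entity_node = vapply(unique(meas), one, "", p = V("is_about")),
    trt_node = vapply(unique(meas), one, "", p = V("has_treatment")),
    qt_node = vapply(unique(meas), one, "", p = V("has_quantitation_type")),
    value = as.numeric(vapply(unique(meas), one, "", p = V("has_value"))),
    unit = vapply(unique(meas), one, "", p = V("has_unit")))
  rec$entity <- vapply(rec$entity_node, function(s) .g_label(g, s), "")
  rec$treatment <- vapply(rec$trt_node, function(s) .g_label(g, s), "")
  mean_iri <- V("sample_mean")
  sem_iri <- V("standard_error_of_mean")
  qt_type <- vapply(rec$qt_node, function(s) {
    tps <- .g_objects(g, s = s, p = .rdf_type)
    if (mean_iri %in% tps) "mean" else if (sem_iri %in% tps) "sem" else "other"
  }, "")
  rec$stat <- qt_type
  if (!is.null(treatments)) rec <- rec[rec$treatment %in% treatments, , drop = FALSE]
  rec <- rec[rec$stat %in% c("mean", "sem"), , drop = FALSE]
  if (!nrow(rec)) {
    return(tibble::tibble(entity = character(), treatment = character(),
                          mean = double(), sem = double(), unit = character()))
  }
  wide <- tidyr::pivot_wider(
    rec[, c("entity", "treatment", "trt_node", "unit", "stat", "value")],
    names_from = "stat", values_from = "value")
  if (!"mean" %in% names(wide)) wide$mean <- NA_real_
  if (!"sem" %in% names(wide)) wide$sem <- NA_real_
  # explode the treatment node into one column per variable
  p_hfl <- V("has_factor_level")
  p_mov <- V("member_of_variable")
  lev_var <- stats::setNames(
    vapply(g$object[g$predicate == p_hfl], function(l)
      .g_label(g, one(l, p_mov)), ""),
    g$object[g$predicate == p_hfl])
  lev_lab <- stats::setNames(
    vapply(names(lev_var), function(l) .g_label(g, l), ""), names(lev_var))
  fac_names <- unique(unname(lev_var))
  for (f in fac_names) wide[[f]] <- NA_character_
  for (i in seq_len(nrow(wide))) {
    levs <- .g_objects(g, s = wide$trt_node[i], p = p_hfl)
    for (l in levs) wide[[lev_var[[l]]]][i] <- lev_lab[[l]]
  }
  out <- wide[, c("entity", fac_names, "treatment", "mean", "sem", "unit"),
              drop = FALSE]
  dplyr::arrange(out, .data$entity, .data$treatment)
}
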