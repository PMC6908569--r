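# Deterministic synthetic-study generator.
#
# Emulates the structure of a targeted metabolite profiling supplementary
# table: 61 compounds in rows, composed "<cultivar> <part> — <statistic>"
# column headers over a cultivar (6 levels) x organism-part (3 levels)
# design of which 8 of the 18 combinations are observed (every cultivar at
# sepal, plus the reference cultivar at every part), with sample-mean and
# SEM columns computed over n = 3 technical replicates. Concentrations are
# log-normal: positive and right-skewed, as metabolite abundances are. The
# generator reproduces the *structure* of such a table, never any real
# study's values, and every bundle ships with a ground-truth object so
# downstream modules can be verified without re-deriving anything from the
# files.

.default_cultivars <- c("Old Blush", "Damask Pearl", "Crimson Rambler",
                        "Tea Noisette", "Maiden Blush", "Autumn Damask")
.default_parts <- c("sepal", "petal", "stamen")
.part_tokens <- c(sepal = "sepals", petal = "petals", stamen = "stamens")
.anatomy_accessions <- c(sepal = "PO:0009031", petal = "PO:0009032",
                         stamen = "PO:0009029")

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic-study generator
#'
#' Defaults are the exemplar study conditions: 61 metabolites, cultivar
#' (6 levels) x organism part (3 levels), 8 of 18 combinations observed,
#' sample mean + SEM over n = 3 technical replicates.
#'
#' @param n_entities Number of molecular entities (rows).
#' @param cultivars,parts Level labels of the two factors.
#' @param factor_names Names of the two factors.
#' @param layout `"fractional"` (all cultivars at the first part, plus the
#'   reference cultivar at all parts) or `"full"` (complete cross).
#' @param reference_cultivar Cultivar observed in every part under the
#'   fractional layout.
#' @param sample_size Replicates behind each summary statistic.
#' @param replicate_semantics `"technical"` by default: one biomaterial
#'   assayed repeatedly, so the SEM estimates measurement variability.
#' @param unit Concentration unit string (carried verbatim).
#' @param missing_rate Probability that a cell is missing.
#' @param n_unresolved Number of entities withheld from the chemical term
#'   map (they will annotate as unresolved).
#' @param accession_offset Offset for synthetic CHEBI-style accessions
#'   (used by [generate_pair()] to keep studies disjoint).
#' @param entities Optional tibble (`label`, `curie`, `inchi`) overriding
#'   the generated entity list.
#' @param value_location,value_spread,effect_scale Log-scale location, per-
#'   entity spread and per-treatment effect scale of the log-normal value
#'   model.
#' @param seed RNG seed; the whole bundle is a pure function of
#'   (params, seed).
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(n_entities = 61L,
                           cultivars = .default_cultivars,
                           parts = .default_parts,
                           factor_names = c("rose cultivar", "organism part"),
                           layout = c("fractional", "full"),
                           reference_cultivar = cultivars[1],
                           sample_size = 3L,
                           replicate_semantics = "technical",
                           unit = "ng g-1",
                           missing_rate = 0,
                           n_unresolved = 0L,
                           accession_offset = 0L,
                           entities = NULL,
                           value_location = log(100),
                           value_spread = 0.8,
                           effect_scale = 0.3,
                           seed = 42L) {
  layout <- match.arg(layout)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  }
  if (length(cultivars) < 1L || length(parts) < 1L) {
    stop("each factor needs at least one level", call. = FALSE)
  }
  if (n_unresolved > n_entities) {
    stop("n_unresolved cannot exceed n_entities", call. = FALSE)
  }
  structure(as.list(environment()), class = "fixture_params")
}

.fixture_entities <- function(params) {
  if (!is.null(params$entities)) return(tibble::as_tibble(params$entities))
  n <- params$n_entities
  named <- c("geraniol", "β-ionone", "2-phenylethanol")
  labels <- c(named, sprintf("compound %03d", seq_len(max(0L, n - length(named))) +
                               length(named)))[seq_len(n)]
  idx <- seq_len(n) + params$accession_offset
  tibble::tibble(
    label = labels,
    curie = sprintf("CHEBI:9%05d", idx),
    inchi = sprintf("InChI=1S/synthetic-fixture-%05d", idx))
}

.fixture_layout <- function(params) {
  if (params$layout == "full") {
    grid <- cartesian_treatments(stats::setNames(
      list(params$cultivars, params$parts), params$factor_names))
    return(grid[, params$factor_names, drop = FALSE])
  }
  ref <- params$reference_cultivar
  first_part <- params$parts[1]
  a <- tibble::tibble(c = params$cultivars, p = first_part)
  b <- tibble::tibble(c = ref, p = setdiff(params$parts, first_part))
  out <- dplyr::distinct(dplyr::bind_rows(a, b))
  names(out) <- params$factor_names
  out
}

.fixture_term_maps <- function(params, ents) {
  keep <- seq_len(nrow(ents) - params$n_unresolved)
  chem_entries <- stats::setNames(
    lapply(keep, function(i) list(curie = ents$curie[i], label = ents$label[i],
                                  inchi = ents$inchi[i])),
    ents$label[keep])
  taxon_entries <- stats::setNames(
    lapply(seq_along(params$cultivars), function(i)
      list(curie = sprintf("NCBITaxon:9%05d", i + 74000L),
           label = params$cultivars[i])),
    params$cultivars)
  anat_entries <- stats::setNames(
    lapply(params$parts, function(p)
      list(curie = .anatomy_accessions[[p]] %||%
             sprintf("PO:00099%02d", match(p, params$parts)),
           label = p)),
    params$parts)
  stat_entries <- list(
    "average" = list(curie = "STATO:0000401", label = "sample mean"),
    "standard error" = list(curie = "STATO:0000037",
                            label = "standard error of the mean"))
  list(
    chemical = term_map("chemical", chem_entries, ontology = "CHEBI",
                        version = "synthetic-fixture"),
    taxon = term_map("taxon", taxon_entries, ontology = "NCBITaxon",
                     version = "synthetic-fixture"),
    anatomy = term_map("anatomy", anat_entries, ontology = "PO",
                       version = "synthetic-fixture"),
    statistic = term_map(
      "statistic", stat_entries,
      synonyms = c("mean" = "average", "avg" = "average",
                   "sem" = "standard error", "se" = "standard error",
                   "std error" = "standard error"),
      ontology = "STATO", version = "synthetic-fixture"))
}

.fixture_header_spec <- function(params) {
  part_tokens <- vapply(params$parts, function(p)
    .part_tokens[[p]] %||% paste0(p, "s"), "")
  syn <- stats::setNames(params$parts, part_tokens)
  syn <- c(syn, stats::setNames(params$cultivars, params$cultivars))
  pattern <- sprintf("^(.+) (%s) - (average|standard error)$",
                     paste(part_tokens, collapse = "|"))
  header_spec(
    factors = params$factor_names,
    rules = list(list(pattern = pattern,
                      assign = c(params$factor_names, "qtype"))),
    synonyms = syn,
    qtype_map = c("average" = "sample_mean",
                  "standard error" = "standard_error_of_mean"),
    unit = params$unit,
    sample_size = params$sample_size,
    replicate_semantics = params$replicate_semantics)
}

#' Generate a synthetic study bundle
#'
#' Writes a wide matrix CSV (composed headers, em-dash statistic
#' separator), the matching header spec and the four term maps, and
#' returns a ground-truth object holding the expected cube, design model
#' and per-cell dispersions. Identical params produce byte-identical
#' files. SEM columns are per-treatment dispersion / sqrt(sample_size), so
#' the mean/SEM relationship is internally consistent.
#'
#' @param params A [fixture_params()].
#' @param dir Output directory.
#' @return A `fixture_truth` list: `params`, `files` (named paths),
#'   `cube` (annotated), `design`, `header_spec`, `term_maps`,
#'   `dispersions`.
#' @export
generate_study <- function(params = fixture_params(), dir) {
  stopifnot(inherits(params, "fixture_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ents <- .fixture_entities(params)
  n <- nrow(ents)
  obs <- .fixture_layout(params)
  n_trt <- nrow(obs)
  tid <- do.call(paste, c(unname(as.list(obs)), sep = " | "))

  vals <- .with_seed(params$seed, {
    mu <- stats::rnorm(n, params$value_location, params$value_spread)
    eff <- stats::rnorm(n_trt, 0, params$effect_scale)
    noise <- matrix(stats::rnorm(n * n_trt, 0, 0.1), n, n_trt)
    mean_mat <- signif(exp(outer(mu, eff, `+`) + noise), 6)
    cv <- matrix(stats::runif(n * n_trt, 0.05, 0.2), n, n_trt)
    sem_mat <- signif(mean_mat * cv / sqrt(params$sample_size), 6)
    miss <- matrix(stats::runif(n * 2 * n_trt) < params$missing_rate,
                   n, 2 * n_trt)
    list(mean = mean_mat, sem = sem_mat, miss = miss)
  })
  mean_mat <- vals$mean
  sem_mat <- vals$sem
  # column block per treatment: (average, standard error)
  part_tokens <- vapply(obs[[params$factor_names[2]]], function(p)
    .part_tokens[[p]] %||% paste0(p, "s"), "")
  headers <- character(0)
  cols <- list()
  for (t in seq_len(n_trt)) {
    h_base <- paste(obs[[params$factor_names[1]]][t], part_tokens[t])
    for (s in c("average", "standard error")) {
      j <- length(cols) + 1L
      v <- if (s == "average") mean_mat[, t] else sem_mat[, t]
      v[vals$miss[, j]] <- NA_real_
      headers <- c(headers, paste0(h_base, " — ", s))
      cols[[j]] <- v
    }
  }
  wide <- tibble::as_tibble(stats::setNames(cols, headers))
  wide <- dplyr::bind_cols(tibble::tibble(compound = ents$label), wide)
  matrix_path <- file.path(dir, "matrix.csv")
  .write_csv_lines(wide, matrix_path)

  spec <- .fixture_header_spec(params)
  spec_path <- file.path(dir, "header_spec.yaml")
  write_header_spec(spec, spec_path)
  maps <- .fixture_term_maps(params, ents)
  map_paths <- vapply(names(maps), function(d) {
    p <- file.path(dir, paste0("term-map-", d, ".yaml"))
    write_term_map(maps[[d]], p)
    p
  }, "")

  # ground-truth cube, built directly (not through ingest)
  resolved <- seq_len(n) <= n - params$n_unresolved
  entities <- tibble::tibble(
    input_label = ents$label,
    normalized_label = normalize_label(ents$label),
    curie = ifelse(resolved, ents$curie, NA_character_),
    iri = ifelse(resolved, vapply(ents$curie, curie_to_iri, ""), NA_character_),
    term_label = ifelse(resolved, ents$label, NA_character_),
    inchi = ifelse(resolved, ents$inchi, NA_character_),
    resolution = ifelse(resolved, "resolved", "unresolved"))
  factors <- tibble::tibble(name = params$factor_names)
  lv1 <- unique(obs[[params$factor_names[1]]])
  lv2 <- unique(obs[[params$factor_names[2]]])
  taxon_cu <- vapply(lv1, function(l)
    maps$taxon$entries[[normalize_label(l)]]$curie, "")
  anat_cu <- vapply(lv2, function(l)
    maps$anatomy$entries[[normalize_label(l)]]$curie, "")
  levels <- dplyr::bind_rows(
    tibble::tibble(factor_name = params$factor_names[1], label = lv1,
                   curie = taxon_cu,
                   iri = vapply(taxon_cu, curie_to_iri, ""), term_label = lv1),
    tibble::tibble(factor_name = params$factor_names[2], label = lv2,
                   curie = anat_cu,
                   iri = vapply(anat_cu, curie_to_iri, ""), term_label = lv2))
  treatments <- dplyr::bind_cols(
    tibble::tibble(treatment_id = tid, status = "observed"), obs)
  qtypes <- tibble::tibble(
    input_label = c("average", "standard error"),
    canonical_name = c("sample_mean", "standard_error_of_mean"),
    requires_sample_size = TRUE,
    curie = c("STATO:0000401", "STATO:0000037"),
    iri = vapply(c("STATO:0000401", "STATO:0000037"), curie_to_iri, ""),
    term_label = c("sample mean", "standard error of the mean"))
  meas <- vector("list", 2L * n_trt)
  for (t in seq_len(n_trt)) {
    for (k in 1:2) {
      j <- (t - 1L) * 2L + k
      meas[[j]] <- tibble::tibble(
        entity = entities$normalized_label,
        treatment_id = tid[t],
        qtype = qtypes$input_label[k],
        value = cols[[j]],
        unit = params$unit,
        sample_size = params$sample_size,
        replicate_semantics = params$replicate_semantics)
    }
  }
  cube <- data_cube(study_id = basename(dir), entities = entities,
                    factors = factors, levels = levels,
                    treatments = treatments, qtypes = qtypes,
                    measurements = dplyr::bind_rows(meas),
                    provenance = "synthetic fixture bundle")
  # the full level sets define the theoretical space
  full_levels <- level_table(dplyr::bind_rows(
    tibble::tibble(factor_name = params$factor_names[1], label = params$cultivars),
    tibble::tibble(factor_name = params$factor_names[2], label = params$parts)))
  design_cube <- cube
  design_cube$levels <- dplyr::rows_update(
    full_levels, cube$levels, by = c("factor_name", "label"))
  design <- infer_design(design_cube)
  dispersions <- tibble::tibble(
    entity = rep(entities$normalized_label, n_trt),
    treatment_id = rep(tid, each = n),
    dispersion = as.vector(sem_mat) * sqrt(params$sample_size))
  structure(
    list(params = params,
         files = c(matrix = matrix_path, header_spec = spec_path, map_paths),
         cube = cube, design = design, header_spec = spec, term_maps = maps,
         dispersions = dispersions),
    class = "fixture_truth")
}

#' Generate a pair of studies with a planted metabolite overlap
#'
#' Exactly `n_shared` entities carry identical chemical identifiers
#' (label, CURIE, InChI) in both studies; the rest are disjoint. The truth
#' object records the three disjoint region counts.
#'
#' @param params_a,params_b [fixture_params()] for the two studies.
#' @param n_shared Number of entities shared between the studies.
#' @param dir Output directory (subdirectories `study_a`, `study_b`).
#' @return List with `a`, `b` (fixture truths) and `regions`
#'   (`shared`, `a_only`, `b_only`).
#' @export
generate_pair <- function(params_a = fixture_params(),
                          params_b = fixture_params(n_entities = 50L, seed = 43L),
                          n_shared = 40L, dir) {
  if (n_shared > min(params_a$n_entities, params_b$n_entities)) {
    stop("n_shared exceeds the smaller study's entity count", call. = FALSE)
  }
  ents_a <- .fixture_entities(params_a)
  n_b <- params_b$n_entities
  fresh <- fixture_params(n_entities = n_b - n_shared,
                          accession_offset = params_a$n_entities + 500L)
  ents_b_new <- .fixture_entities(fresh)
  ents_b_new$label <- sprintf("compound B-%03d", seq_len(nrow(ents_b_new)))
  ents_b <- dplyr::bind_rows(ents_a[seq_len(n_shared), , drop = FALSE],
                             ents_b_new)
  params_a$entities <- ents_a
  params_b$entities <- ents_b
  a <- generate_study(params_a, file.path(dir, "study_a"))
  b <- generate_study(params_b, file.path(dir, "study_b"))
  list(a = a, b = b,
       regions = c(shared = n_shared,
                   a_only = params_a$n_entities - n_shared,
                   b_only = n_b - n_shared))
}

#' Generate a study bundle for an arbitrary crossed categorical design
#'
#' Generalization of [generate_study()] to any number of factors: headers
#' are `"<level> / <level> / ... — <statistic>"`, one sample-mean and one
#' SEM column per observed treatment. Used to exercise design inference
#' across factor/level sweeps; level labels must not contain `" / "`.
#'
#' @param levels_by_factor Named list of character level vectors, in
#'   factor declaration order.
#' @param observed Character vector of treatment ids (`" | "`-joined
#'   tuples) to observe; `NULL` observes the full cartesian product.
#' @param n_entities Number of entities.
#' @param dir Output directory.
#' @param sample_size,unit,replicate_semantics,seed As in
#'   [fixture_params()].
#' @return A `fixture_truth` list (`cube` unannotated, `design`, `files`,
#'   `header_spec`).
#' @export
generate_design_study <- function(levels_by_factor, observed = NULL,
                                  n_entities = 5L, dir,
                                  sample_size = 3L, unit = "ng g-1",
                                  replicate_semantics = "technical",
                                  seed = 42L) {
  stopifnot(is.list(levels_by_factor), length(levels_by_factor) >= 1L,
            !is.null(names(levels_by_factor)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  theo <- cartesian_treatments(levels_by_factor)
  if (is.null(observed)) observed <- theo$treatment_id
  stray <- setdiff(observed, theo$treatment_id)
  if (length(stray)) stop("observed ids outside the cartesian product: ",
                          paste(stray, collapse = ", "), call. = FALSE)
  obs <- theo[match(observed, theo$treatment_id), , drop = FALSE]
  fac <- names(levels_by_factor)
  n_trt <- nrow(obs)
  ent_labels <- sprintf("compound %03d", seq_len(n_entities))
  vals <- .with_seed(seed, {
    mean_mat <- signif(matrix(stats::rlnorm(n_entities * n_trt, log(50), 0.6),
                              n_entities, n_trt), 6)
    sem_mat <- signif(mean_mat *
                        matrix(stats::runif(n_entities * n_trt, 0.05, 0.2),
                               n_entities, n_trt) / sqrt(sample_size), 6)
    list(mean = mean_mat, sem = sem_mat)
  })
  headers <- character()
  cols <- list()
  for (t in seq_len(n_trt)) {
    h_base <- paste(vapply(fac, function(f) obs[[f]][t], ""), collapse = " / ")
    for (s in c("average", "standard error")) {
      headers <- c(headers, paste0(h_base, " — ", s))
      cols[[length(cols) + 1L]] <-
        if (s == "average") vals$mean[, t] else vals$sem[, t]
    }
  }
  wide <- dplyr::bind_cols(tibble::tibble(compound = ent_labels),
                           tibble::as_tibble(stats::setNames(cols, headers)))
  matrix_path <- file.path(dir, "matrix.csv")
  .write_csv_lines(wide, matrix_path)
  pattern <- paste0("^", paste(rep("(.+?)", length(fac)), collapse = " / "),
                    " - (average|standard error)$")
  spec <- header_spec(
    factors = fac,
    rules = list(list(pattern = pattern, assign = c(fac, "qtype"))),
    synonyms = stats::setNames(unlist(levels_by_factor, use.names = FALSE),
                               unlist(levels_by_factor, use.names = FALSE)),
    unit = unit, sample_size = sample_size,
    replicate_semantics = replicate_semantics)
  spec_path <- file.path(dir, "header_spec.yaml")
  write_header_spec(spec, spec_path)

  entities <- entity_table(tibble::tibble(input_label = ent_labels))
  levels_tbl <- dplyr::bind_rows(lapply(fac, function(f)
    tibble::tibble(factor_name = f, label = levels_by_factor[[f]])))
  treatments <- dplyr::bind_cols(
    tibble::tibble(treatment_id = obs$treatment_id, status = "observed"),
    obs[, fac, drop = FALSE])
  qtypes <- qtype_table(tibble::tibble(
    input_label = c("average", "standard error"),
    canonical_name = c("sample_mean", "standard_error_of_mean"),
    requires_sample_size = TRUE))
  meas <- list()
  for (t in seq_len(n_trt)) {
    for (k in 1:2) {
      meas[[length(meas) + 1L]] <- tibble::tibble(
        entity = entities$normalized_label,
        treatment_id = obs$treatment_id[t],
        qtype = qtypes$input_label[k],
        value = cols[[(t - 1L) * 2L + k]],
        unit = unit, sample_size = sample_size,
        replicate_semantics = replicate_semantics)
    }
  }
  cube <- data_cube(study_id = basename(dir), entities = entities,
                    factors = tibble::tibble(name = fac), levels = levels_tbl,
                    treatments = treatments, qtypes = qtypes,
                    measurements = dplyr::bind_rows(meas),
                    provenance = "synthetic generic-design bundle")
  structure(
    list(params = list(levels_by_factor = levels_by_factor,
                       observed = observed, n_entities = n_entities,
                       sample_size = sample_size, seed = seed),
         files = c(matrix = matrix_path, header_spec = spec_path),
         cube = cube, design = infer_design(cube), header_spec = spec,
         term_maps = NULL, dispersions = NULL),
    class = "fixture_truth")
}

.known_perturbations <- c("header_case", "header_quotes", "header_whitespace",
                          "non_numeric_cells", "ragged_rows", "missing_tokens")

#' Perturb a generated matrix to emulate messy retrospective data
#'
#' Applies declared perturbations to a bundle's matrix file and returns a
#' manifest of the findings the ingest layer must produce. Header noise
#' (case, typographic quotes, stray whitespace) must be absorbed by
#' normalization; injected non-numeric cells must each yield a
#' lenient-mode value finding; a ragged row must be a structural error.
#' The rewriter assumes the fixture's own field content (no embedded
#' delimiters), which holds for every generated bundle.
#'
#' @param bundle A `fixture_truth` from [generate_study()].
#' @param perturbations Named list drawn from `header_case`,
#'   `header_quotes`, `header_whitespace` (logicals), `non_numeric_cells`,
#'   `ragged_rows`, `missing_tokens` (counts).
#' @param path Output file for the perturbed matrix.
#' @param seed Seed for choosing perturbed cells.
#' @return List with `matrix` (path) and `manifest`: expected findings
#'   tibble, `structural_error` flag, `n_missing_injected`.
#' @export
generate_messy_variant <- function(bundle, perturbations = list(),
                                   path, seed = 1L) {
  stopifnot(inherits(bundle, "fixture_truth"))
  unknown <- setdiff(names(perturbations), .known_perturbations)
  if (length(unknown)) {
    stop("unknown perturbation(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(
    list(header_case = FALSE, header_quotes = FALSE, header_whitespace = FALSE,
         non_numeric_cells = 0L, ragged_rows = 0L, missing_tokens = 0L),
    perturbations)
  lines <- readLines(bundle$files[["matrix"]], encoding = "UTF-8")
  header <- lines[1]
  body <- lines[-1]
  if (isTRUE(p$header_case)) header <- toupper(header)
  if (isTRUE(p$header_quotes)) {
    toks <- vapply(bundle$params$parts, function(x)
      .part_tokens[[x]] %||% paste0(x, "s"), "")
    header <- gsub(sprintf("(^|,)([^,]+?) (%s)", paste(toks, collapse = "|")),
                   "\\1‘\\2’ \\3", header)
  }
  if (isTRUE(p$header_whitespace)) header <- gsub(" ", "  ", header, fixed = TRUE)
  cells <- strsplit(body, ",", fixed = TRUE)
  n_row <- length(cells)
  n_col <- length(cells[[1]])
  findings <- tibble::tibble(code = character(), count = integer())
  .with_seed(seed, {
    if (p$non_numeric_cells > 0L) {
      pick <- sample(n_row * (n_col - 1L), p$non_numeric_cells)
      for (q in pick) {
        r <- (q - 1L) %% n_row + 1L
        cc <- (q - 1L) %/% n_row + 2L
        cells[[r]][cc] <- "not detected!"
      }
      findings <- dplyr::bind_rows(findings, tibble::tibble(
        code = "NON_NUMERIC_CELL", count = as.integer(p$non_numeric_cells)))
    }
    if (p$missing_tokens > 0L) {
      pick <- sample(n_row * (n_col - 1L), p$missing_tokens)
      for (q in pick) {
        r <- (q - 1L) %% n_row + 1L
        cc <- (q - 1L) %/% n_row + 2L
        cells[[r]][cc] <- "nd"
      }
    }
    if (p$ragged_rows > 0L) {
      pick <- sample(n_row, p$ragged_rows)
      for (r in pick) cells[[r]] <- cells[[r]][-length(cells[[r]])]
    }
  })
  out <- c(header, vapply(cells, paste, "", collapse = ","))
  con <- file(path, open = "wb")
  writeLines(out, con, sep = "\n")
  close(con)
  list(matrix = path,
       manifest = list(expected_findings = findings,
                       structural_error = p$ragged_rows > 0L,
                       n_missing_injected = as.integer(p$missing_tokens)))
}
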