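# Shared builders: a hand-made minimal cube and a randomized small-cube
# generator used by the round-trip / oracle property tests.

tiny_cube <- function(study_id = "tiny") {
  data_cube(
    study_id = study_id,
    entities = tibble::tibble(input_label = c("Geraniol", "Nerol")),
    factors = tibble::tibble(name = "tissue"),
    levels = tibble::tibble(factor_name = "tissue", label = c("sepal", "petal")),
    treatments = tibble::tibble(treatment_id = c("sepal", "petal"),
                                status = "observed",
                                tissue = c("sepal", "petal")),
    qtypes = tibble::tibble(input_label = "average",
                            canonical_name = "sample_mean",
                            requires_sample_size = TRUE),
    measurements = tibble::tibble(
      entity = c("geraniol", "geraniol", "nerol", "nerol"),
      treatment_id = c("sepal", "petal", "sepal", "petal"),
      qtype = "average", value = c(1.5, 2.5, 3.5, 4.5),
      unit = "ng g-1", sample_size = 3L,
      replicate_semantics = "technical"))
}

# Randomized small cube: 1-3 factors with 1-3 levels, random observed
# subset, 1-4 entities (some annotated), 1-2 qtypes, some missing cells.
random_cube <- function(seed) {
  set.seed(seed)
  n_fac <- sample(1:3, 1)
  fac_names <- paste0("factor_", seq_len(n_fac))
  lv <- lapply(seq_len(n_fac), function(i)
    paste0("f", i, "l", seq_len(sample(1:3, 1))))
  names(lv) <- fac_names
  theo <- cartesian_treatments(lv)
  n_obs <- sample(seq_len(nrow(theo)), 1)
  obs <- theo[sort(sample(nrow(theo), n_obs)), , drop = FALSE]
  obs$status <- "observed"
  n_ent <- sample(1:4, 1)
  ent_labels <- paste0("cmpd ", seq_len(n_ent))
  resolved <- stats::runif(n_ent) < 0.5
  entities <- tibble::tibble(
    input_label = ent_labels,
    curie = ifelse(resolved, sprintf("CHEBI:%05d", seq_len(n_ent)), NA),
    iri = ifelse(resolved,
                 vapply(sprintf("CHEBI:%05d", seq_len(n_ent)), curie_to_iri, ""),
                 NA),
    inchi = ifelse(resolved, sprintf("InChI=1S/synthetic-%d", seq_len(n_ent)), NA),
    resolution = ifelse(resolved, "resolved", "unresolved"))
  qt <- tibble::tibble(
    input_label = c("average", "standard error")[seq_len(sample(1:2, 1))],
    canonical_name = c("sample_mean", "standard_error_of_mean")[
      seq_len(length(input_label))],
    requires_sample_size = TRUE)
  grid <- expand.grid(entity = normalize_label(ent_labels),
                      treatment_id = obs$treatment_id,
                      qtype = qt$input_label, stringsAsFactors = FALSE)
  vals <- signif(stats::rlnorm(nrow(grid), log(20), 1), 6)
  vals[stats::runif(nrow(grid)) < 0.1] <- NA
  meas <- tibble::tibble(
    entity = grid$entity, treatment_id = grid$treatment_id,
    qtype = grid$qtype, value = vals, unit = "ng g-1",
    sample_size = 3L, replicate_semantics = "technical")
  data_cube(study_id = paste0("rand", seed), entities = entities,
            factors = tibble::tibble(name = fac_names),
            levels = dplyr::bind_rows(lapply(fac_names, function(f)
              tibble::tibble(factor_name = f, label = lv[[f]]))),
            treatments = obs[, c("treatment_id", "status", fac_names)],
            qtypes = qt, measurements = meas)
}

# bundle loader: ingest + annotate one generated study directory
ingest_bundle <- function(dir, study_id = basename(dir), mode = "strict") {
  m <- suppressMessages(read_matrix(file.path(dir, "matrix.csv")))
  spec <- read_header_spec(file.path(dir, "header_spec.yaml"))
  cube <- unpack_headers(m, spec, study_id = study_id, mode = mode)
  map_files <- Sys.glob(file.path(dir, "term-map-*.yaml"))
  if (!length(map_files)) return(cube)
  maps <- lapply(map_files, read_term_map)
  annotate_cube(cube, maps,
                routing = c("rose cultivar" = "taxon",
                            "organism part" = "anatomy"))$cube
}
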