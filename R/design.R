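# Experimental-design inference: theoretical treatment space by cartesian
# product, observed subset, and classification (single-factor / full /
# fractional factorial). Only crossed categorical factors are modelled.

#' Enumerate the theoretical treatment space
#'
#' Cartesian product of the factor level sets, in lexicographic order of
#' (factor declaration order, level order): the first factor varies
#' slowest. The count equals the product of the level-set sizes.
#'
#' @param factors Named list of character vectors (factor name -> ordered
#'   level labels), or a [data_cube()] whose declared levels are used.
#' @return Tibble with one column per factor plus `treatment_id` and
#'   `status = "theoretical"`.
#' @export
cartesian_treatments <- function(factors) {
  if (inherits(factors, "data_cube")) factors <- cube_factor_levels(factors)
  if (!is.list(factors) || length(factors) == 0L) {
    stop("no factors supplied: a design needs at least one factor", call. = FALSE)
  }
  n_lev <- vapply(factors, length, 0L)
  if (any(n_lev == 0L)) {
    stop("factor(s) with zero levels: ",
         paste(names(factors)[n_lev == 0L], collapse = ", "), call. = FALSE)
  }
  # expand.grid varies its first argument fastest; reverse both ways so the
  # first declared factor varies slowest.
  grid <- expand.grid(rev(factors), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- tibble::as_tibble(grid[, rev(seq_along(factors)), drop = FALSE])
  names(grid) <- names(factors)
  grid$treatment_id <- do.call(paste, c(unname(as.list(grid)), sep = " | "))
  grid$status <- "theoretical"
  grid[, c("treatment_id", "status", names(factors)), drop = FALSE]
}

#' Infer the design model of a cube
#'
#' Computes the theoretical treatment space from the cube's factor level
#' sets, marks the observed subset, classifies the design and attaches
#' per-treatment group sizes.
#'
#' Classification: `single_factor` with exactly one factor;
#' `full_factorial` when two or more factors are fully crossed and every
#' combination is observed; `fractional_factorial` when only a strict,
#' non-empty subset of the cartesian product is observed.
#'
#' @param cube A valid [data_cube()] with at least one factor.
#' @param replicate_semantics Override for the cube's replicate semantics
#'   (`"technical"`, `"biological"`, `"unspecified"`).
#' @param sample_sizes A single integer broadcast to every observed
#'   treatment, or a named integer vector keyed by treatment id; defaults
#'   to the sizes recorded on the cube's measurements.
#' @return A `design_model` object.
#' @export
infer_design <- function(cube, replicate_semantics = NULL, sample_sizes = NULL) {
  stopifnot(inherits(cube, "data_cube"))
  if (nrow(cube$factors) == 0L) {
    stop("cube declares no factors; cannot infer a design", call. = FALSE)
  }
  theo <- cartesian_treatments(cube)
  obs_ids <- cube$treatments$treatment_id[cube$treatments$status == "observed"]
  stray <- setdiff(obs_ids, theo$treatment_id)
  if (length(stray)) {
    stop("observed treatment(s) outside the theoretical space: ",
         paste0("'", stray, "'", collapse = ", "), call. = FALSE)
  }
  observed <- theo[theo$treatment_id %in% obs_ids, , drop = FALSE]
  observed$status <- "observed"
  n_theo <- nrow(theo)
  n_obs <- nrow(observed)
  n_factors <- nrow(cube$factors)
  classification <- if (n_factors == 1L) {
    "single_factor"
  } else if (n_obs == n_theo) {
    "full_factorial"
  } else if (n_obs > 0L) {
    "fractional_factorial"
  } else {
    stop("cube observes no treatments; design classification is undefined",
         call. = FALSE)
  }
  if (is.null(replicate_semantics)) {
    rs <- unique(cube$measurements$replicate_semantics)
    replicate_semantics <- if (length(rs) == 1L) rs else "unspecified"
  }
  if (is.null(sample_sizes)) {
    gs <- stats::setNames(rep(NA_integer_, n_obs), observed$treatment_id)
    for (tid in observed$treatment_id) {
      n <- unique(stats::na.omit(
        cube$measurements$sample_size[cube$measurements$treatment_id == tid]))
      if (length(n) == 1L) gs[[tid]] <- n
    }
  } else if (length(sample_sizes) == 1L && is.null(names(sample_sizes))) {
    gs <- stats::setNames(rep(as.integer(sample_sizes), n_obs),
                          observed$treatment_id)
  } else {
    gs <- stats::setNames(as.integer(sample_sizes[observed$treatment_id]),
                          observed$treatment_id)
  }
  structure(
    list(factors = cube$factors, levels = cube$levels,
         theoretical_treatments = theo, observed_treatments = observed,
         n_theoretical = n_theo, n_observed = n_obs,
         classification = classification, group_sizes = gs,
         replicate_semantics = replicate_semantics),
    class = "design_model")
}

.technical_caveat <- paste(
  "Replicates are technical: the standard error",
  "estimates measurement variability, not biological variability.")

#' Summarise a design model
#'
#' Builds a deterministic report listing each independent variable with its
#' levels (and ontology terms where annotated), the theoretical and
#' observed treatment counts, the classification, group sizes and replicate
#' semantics. When replication is technical the report carries the caveat
#' that the SEM estimates measurement variability, not biological
#' variability.
#'
#' @param d A [infer_design()] result.
#' @param format `"list"` (default), `"json"` (deterministic string) or
#'   `"text"` (plain rendering).
#' @return A list, JSON string, or character vector of lines.
#' @export
design_report <- function(d, format = c("list", "json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(d, "design_model"))
  vars <- lapply(seq_len(nrow(d$factors)), function(i) {
    f <- d$factors$name[i]
    lv <- d$levels[d$levels$factor_name == f, , drop = FALSE]
    v <- list(name = f, n_levels = nrow(lv), levels = lv$label)
    if (!is.na(d$factors$curie[i])) v$term <- d$factors$curie[i]
    terms <- lv$curie[!is.na(lv$curie)]
    if (length(terms)) v$level_terms <- stats::setNames(
      as.list(lv$curie), lv$label)
    v
  })
  rep_list <- list(
    n_variables = nrow(d$factors),
    variables = vars,
    n_theoretical_treatments = d$n_theoretical,
    n_observed_treatments = d$n_observed,
    classification = d$classification,
    group_sizes = as.list(d$group_sizes),
    replicate_semantics = d$replicate_semantics)
  if (d$replicate_semantics == "technical") rep_list$caveat <- .technical_caveat
  if (format == "list") return(rep_list)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(rep_list, auto_unbox = TRUE,
                                         pretty = TRUE, digits = NA)))
  }
  lines <- c(
    sprintf("Design: %s (%d of %d theoretical treatments observed)",
            d$classification, d$n_observed, d$n_theoretical),
    sprintf("Independent variables: %d", nrow(d$factors)))
  for (v in vars) {
    lines <- c(lines, sprintf("  - %s: %d levels (%s)", v$name, v$n_levels,
                              paste(v$levels, collapse = ", ")))
  }
  gs <- unique(stats::na.omit(d$group_sizes))
  lines <- c(lines,
             if (length(gs) == 1L) sprintf("Group size: n = %d per treatment", gs)
             else "Group sizes: per-treatment (see JSON report)",
             sprintf("Replicate semantics: %s", d$replicate_semantics))
  if (d$replicate_semantics == "technical") lines <- c(lines, .technical_caveat)
  lines
}

#' @export
print.design_model <- function(x, ...) {
  cat(design_report(x, format = "text"), sep = "\n")
  invisible(x)
}
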