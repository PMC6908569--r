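# Cross-study metabolite overlap. Entities are joined on the strongest
# identifier available per entity — CURIE first, then InChI, then the
# normalized label — with the key type recorded so mixed-confidence joins
# stay auditable.

#' Identifier keys for every entity of a cube
#'
#' @param cube A [data_cube()].
#' @param policy Ordered key preference; the first available key type is
#'   used per entity.
#' @return Tibble with `entity` (normalized label), `key`, `key_type`
#'   (`"curie"`, `"inchi"`, `"label"`); label keys are the low-confidence
#'   fallback.
#' @export
entity_keys <- function(cube, policy = c("curie", "inchi", "label")) {
  stopifnot(inherits(cube, "data_cube"))
  policy <- match.arg(policy, several.ok = TRUE)
  ent <- cube$entities
  key <- rep(NA_character_, nrow(ent))
  type <- rep(NA_character_, nrow(ent))
  for (p in policy) {
    src <- switch(p, curie = ent$curie, inchi = ent$inchi,
                  label = ent$normalized_label)
    take <- is.na(key) & !is.na(src)
    key[take] <- src[take]
    type[take] <- p
  }
  tibble::tibble(entity = ent$normalized_label, key = key, key_type = type)
}

#' Compare the molecular entities of two studies
#'
#' Computes identifier-keyed membership sets, their intersection and
#' per-study exclusives, an entity x study membership matrix and the three
#' disjoint region counts. The inclusion-exclusion identity
#' `|A u B| = |A| + |B| - |A n B|` holds by construction and is re-checked.
#'
#' @param a,b [data_cube()]s (annotated or not).
#' @param policy Key policy, as in [entity_keys()].
#' @return A `study_comparison` object.
#' @export
compare_studies <- function(a, b, policy = c("curie", "inchi", "label")) {
  ka <- entity_keys(a, policy)
  kb <- entity_keys(b, policy)
  set_a <- unique(stats::na.omit(ka$key))
  set_b <- unique(stats::na.omit(kb$key))
  inter <- sort(intersect(set_a, set_b))
  only_a <- sort(setdiff(set_a, set_b))
  only_b <- sort(setdiff(set_b, set_a))
  union_keys <- sort(union(set_a, set_b))
  stopifnot(length(union_keys) ==
              length(set_a) + length(set_b) - length(inter))
  ids <- c(a$study_id, b$study_id)
  if (ids[1] == ids[2]) ids <- paste0(ids, c(".a", ".b"))
  membership <- tibble::tibble(key = union_keys)
  membership[[ids[1]]] <- union_keys %in% set_a
  membership[[ids[2]]] <- union_keys %in% set_b
  regions <- stats::setNames(
    c(length(inter), length(only_a), length(only_b)),
    c("shared", paste(ids[1], "only"), paste(ids[2], "only")))
  structure(
    list(study_ids = ids, policy = policy,
         keys = list(ka, kb), sets = stats::setNames(list(set_a, set_b), ids),
         intersection = inter,
         exclusives = stats::setNames(list(only_a, only_b), ids),
         membership_matrix = membership, region_counts = regions),
    class = "study_comparison")
}

#' @export
print.study_comparison <- function(x, ...) {
  cat(sprintf("<study_comparison> %s vs %s: shared=%d, exclusives=%d/%d\n",
              x$study_ids[1], x$study_ids[2], x$region_counts[["shared"]],
              length(x$exclusives[[1]]), length(x$exclusives[[2]])))
  invisible(x)
}

#' Disjoint region counts, plot-ready
#'
#' UpSet convention: exclusive (disjoint) regions, not cumulative set
#' sizes, sorted by descending count with lexicographic tie-break on the
#' region label. Feed straight into a bar-chart layer or an UpSet
#' renderer.
#'
#' @param comparison A [compare_studies()] result.
#' @return Tibble with `region`, `degree` (number of studies in the
#'   region), `count`.
#' @export
upset_counts <- function(comparison) {
  stopifnot(inherits(comparison, "study_comparison"))
  rc <- comparison$region_counts
  out <- tibble::tibble(
    region = names(rc),
    degree = c(2L, 1L, 1L),
    count = as.integer(unname(rc)))
  out[order(-out$count, out$region), , drop = FALSE]
}
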