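#' Merge per-herb compound tables and deduplicate by compound id
#'
#' Compound identifiers (not display names) are the stable key: records with
#' the same `compound_id` across tables collapse into one, with herb labels
#' unioned and the first-seen name kept (conflicting names raise a warning).
#' The merged count is the sum of table sizes minus duplicates. The operation
#' is idempotent and, up to record order, commutative and associative.
#'
#' @param tables a list of compound tables (see [compound_table()]).
#' @return A single merged compound table, ordered by first appearance.
#' @export
merge_and_deduplicate <- function(tables) {
  stopifnot(is.list(tables))
  tables <- lapply(tables, validate_compound_table)
  long <- dplyr::bind_rows(lapply(tables, function(tbl) {
    tidyr::unnest(dplyr::rename(tbl, herb = "herbs"), "herb")
  }))
  if (nrow(long) == 0L) return(compound_table())
  long <- dplyr::distinct(long, .data$compound_id, .data$herb, .keep_all = TRUE)
  collapse_compound_rows(long)
}

#' Attach targets to a compound table
#'
#' A plain table join standing in for "target fishing": compounds gain the set
#' of gene symbols they interact with. Every compound in the table appears as
#' a key, with an empty set when it has no recorded interaction; interactions
#' that reference compounds absent from the table are reported and dropped.
#'
#' @param compounds a compound table.
#' @param interactions a normalized interaction tibble
#'   (see [normalize_interactions()]).
#' @return A named list mapping `compound_id` to a character vector of gene
#'   symbols.
#' @export
attach_targets <- function(compounds, interactions) {
  compounds <- validate_compound_table(compounds)
  stopifnot(all(c("compound_id", "target_symbol") %in% names(interactions)))
  unknown <- setdiff(unique(interactions$compound_id), compounds$compound_id)
  if (length(unknown) > 0L) {
    inform(sprintf("%d interaction(s) referencing unknown compound id(s) dropped: %s",
                   sum(interactions$compound_id %in% unknown),
                   paste(unknown, collapse = ", ")))
    interactions <- interactions[!interactions$compound_id %in% unknown, ]
  }
  out <- named(rep(list(character()), nrow(compounds)), compounds$compound_id)
  if (nrow(interactions) > 0L) {
    grouped <- split(interactions$target_symbol, interactions$compound_id)
    out[names(grouped)] <- lapply(grouped, function(x) sort(unique(x)))
  }
  out
}

#' Intersect compound targets with disease gene sets
#'
#' The disease-mapping stage: potential targets are the compound-hit genes
#' that appear in at least one disease gene set (the union over disease sets,
#' not a per-disease intersection); active compounds are those hitting at
#' least one potential target. Per-disease membership is retained for the
#' target-disease edges of the compound-target-disease network.
#'
#' @param compound_targets named list from [attach_targets()].
#' @param diseases a gene-set collection with every set of category
#'   `"DISEASE"`.
#' @param compounds optional compound table; when given, per-herb raw target
#'   sets (unions over each herb's compounds, before disease filtering) are
#'   recorded on the result.
#' @return An object of class `active_set`: a list with elements
#'   `active_compounds`, `potential_targets`, `target_to_diseases`,
#'   `per_herb_targets`.
#' @export
map_to_diseases <- function(compound_targets, diseases, compounds = NULL) {
  diseases <- validate_gene_set_collection(diseases,
                                           attr(diseases, "background"))
  if (nrow(diseases) == 0L) {
    abort("disease collection is empty: at least one disease gene set is required")
  }
  if (any(diseases$category != "DISEASE")) {
    abort("every set in the disease collection must have category DISEASE")
  }
  disease_union <- unique(unlist(diseases$members))
  all_targets <- unique(unlist(compound_targets))
  potential <- sort(intersect(all_targets, disease_union))
  hits <- vapply(compound_targets,
                 function(tg) length(intersect(tg, potential)) > 0L,
                 logical(1))
  active <- names(compound_targets)[hits]
  target_to_diseases <- lapply(named(potential, potential), function(t) {
    sort(diseases$set_id[vapply(diseases$members, function(m) t %in% m,
                                logical(1))])
  })
  per_herb <- list()
  if (!is.null(compounds)) {
    compounds <- validate_compound_table(compounds)
    long <- tidyr::unnest(dplyr::rename(compounds, herb = "herbs"), "herb")
    per_herb <- lapply(split(long$compound_id, long$herb), function(ids) {
      sort(unique(unlist(compound_targets[intersect(ids, names(compound_targets))])))
    })
  }
  structure(
    list(active_compounds = active,
         potential_targets = potential,
         target_to_diseases = target_to_diseases,
         per_herb_targets = per_herb),
    class = "active_set"
  )
}

#' @export
print.active_set <- function(x, ...) {
  cat(sprintf("<active_set> %d active compounds, %d potential targets, %d disease sets\n",
              length(x$active_compounds), length(x$potential_targets),
              length(unique(unlist(x$target_to_diseases)))))
  invisible(x)
}

#' Summarize the screening stages as a count table
#'
#' Reproduces the stage counts a screening report prints: compounds per herb,
#' merged compounds, raw targets per herb, targets common to every herb,
#' pooled unique targets (which obeys inclusion-exclusion:
#' `|A union B| = |A| + |B| - |A intersect B|` for two herbs), active
#' compounds, and potential targets.
#'
#' @param active an `active_set` (with `per_herb_targets` populated when
#'   per-herb counts are wanted).
#' @param compounds optional compound table for per-herb compound counts.
#' @return A tibble with columns `metric`, `value`.
#' @export
stage_summary <- function(active, compounds = NULL) {
  stopifnot(inherits(active, "active_set"))
  rows <- list()
  if (!is.null(compounds)) {
    compounds <- validate_compound_table(compounds)
    long <- tidyr::unnest(dplyr::rename(compounds, herb = "herbs"), "herb")
    per_herb_n <- table(long$herb)
    for (h in names(per_herb_n)) {
      rows[[length(rows) + 1L]] <-
        tibble(metric = paste0("compounds_", h),
               value = as.numeric(per_herb_n[[h]]))
    }
    rows[[length(rows) + 1L]] <-
      tibble(metric = "merged_compounds", value = as.numeric(nrow(compounds)))
  }
  ph <- active$per_herb_targets
  if (length(ph) > 0L) {
    for (h in names(ph)) {
      rows[[length(rows) + 1L]] <-
        tibble(metric = paste0("targets_", h), value = as.numeric(length(ph[[h]])))
    }
    rows[[length(rows) + 1L]] <-
      tibble(metric = "common_targets",
             value = as.numeric(length(Reduce(intersect, ph))))
    rows[[length(rows) + 1L]] <-
      tibble(metric = "pooled_targets",
             value = as.numeric(length(Reduce(union, ph))))
  }
  rows[[length(rows) + 1L]] <-
    tibble(metric = "active_compounds",
           value = as.numeric(length(active$active_compounds)))
  rows[[length(rows) + 1L]] <-
    tibble(metric = "potential_targets",
           value = as.numeric(length(active$potential_targets)))
  dplyr::bind_rows(rows)
}
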