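#' Construct a compound table
#'
#' A compound table is the in-memory form of a TCMSP-style compound inventory:
#' one row per compound with an opaque stable identifier (e.g. `"MOL000675"`),
#' a display name, and the non-empty set of herbs the compound was recorded
#' under. Compound identifiers are unique within a table.
#'
#' @param compound_id character vector of compound identifiers.
#' @param name character vector of display names.
#' @param herbs list of character vectors, one per compound.
#' @return A tibble with columns `compound_id`, `name`, `herbs` (list column).
#' @export
compound_table <- function(compound_id = character(), name = character(),
                           herbs = list()) {
  tbl <- tibble(compound_id = as.character(compound_id),
                name = as.character(name),
                herbs = lapply(herbs, as.character))
  validate_compound_table(tbl)
}

validate_compound_table <- function(tbl) {
  stopifnot(all(c("compound_id", "name", "herbs") %in% names(tbl)))
  if (anyDuplicated(tbl$compound_id)) {
    abort("compound_id values must be unique within a compound table")
  }
  if (nrow(tbl) > 0L && any(lengths(tbl$herbs) == 0L)) {
    abort("every compound must carry at least one herb label")
  }
  as_tibble(tbl)
}

#' Read a per-herb compound table from TSV
#'
#' The file carries one row per (compound, herb) pair with a mandatory header
#' `compound_id`, `name`, `herb`. Rows for the same compound under different
#' herbs merge into a single record holding the union of herb labels; record
#' order follows first appearance in the file. Exact duplicate
#' (compound_id, herb) rows are dropped with a warning.
#'
#' @param path path to a tab-separated file.
#' @return A compound table (see [compound_table()]).
#' @export
read_compound_table <- function(path) {
  df <- read_tsv_strict(path, c("compound_id", "name", "herb"))
  dup <- duplicated(df[c("compound_id", "herb")])
  if (any(dup)) {
    warn(sprintf("'%s': %d duplicate (compound_id, herb) row(s) dropped",
                 path, sum(dup)))
    df <- df[!dup, ]
  }
  collapse_compound_rows(df)
}

# Collapse long-format (compound, herb) rows to one record per compound,
# preserving first-appearance order and keeping the first name seen.
collapse_compound_rows <- function(df) {
  out <- dplyr::summarise(
    df,
    n_names = dplyr::n_distinct(.data$name),  # before `name` masks the column
    name = dplyr::first(.data$name),
    herbs = list(unique(.data$herb)),
    .by = "compound_id"
  )
  if (any(out$n_names > 1L)) {
    warn(sprintf("conflicting names for compound(s) %s; first name kept",
                 paste(out$compound_id[out$n_names > 1L], collapse = ", ")))
  }
  out$n_names <- NULL
  validate_compound_table(out[c("compound_id", "name", "herbs")])
}

#' Write a compound table as a long-format TSV
#'
#' Inverse of [read_compound_table()]: each record is unnested to one row per
#' (compound, herb) pair so the file round-trips through the reader.
#'
#' @param tbl a compound table.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_compound_table <- function(tbl, path) {
  validate_compound_table(tbl)
  long <- tidyr::unnest(dplyr::rename(tbl, herb = "herbs"), "herb")
  write_tsv_plain(long[c("compound_id", "name", "herb")], path)
}

#' Read a compound-target interaction table from TSV
#'
#' Two mandatory columns, `compound_id` and `target_symbol`. Target symbols
#' are normalized to official uppercase symbols, through a symbol map when one
#' is supplied; duplicate (compound, target) pairs after normalization are
#' collapsed.
#'
#' @param path path to a tab-separated file.
#' @param symbol_map optional tibble from [read_symbol_map()].
#' @return A tibble with columns `compound_id`, `target_symbol`.
#' @export
read_interactions <- function(path, symbol_map = NULL) {
  df <- read_tsv_strict(path, c("compound_id", "target_symbol"))
  normalize_interactions(df, symbol_map)
}

#' Normalize an in-memory interaction table
#'
#' @param df tibble with columns `compound_id`, `target_symbol`.
#' @param symbol_map optional symbol map tibble.
#' @return The normalized, deduplicated interaction tibble.
#' @export
normalize_interactions <- function(df, symbol_map = NULL) {
  stopifnot(all(c("compound_id", "target_symbol") %in% names(df)))
  if (nrow(df) > 0L && any(!nzchar(df$target_symbol) | is.na(df$target_symbol))) {
    abort("interaction table contains empty target symbols")
  }
  df$target_symbol <- normalize_symbols(df$target_symbol, symbol_map)
  dplyr::distinct(as_tibble(df[c("compound_id", "target_symbol")]))
}
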