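#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# Roles a network node may carry.
NODE_ROLES <- c("compound", "target", "disease", "pathway", "protein")

# Gene-set categories understood by the collection container.
GENESET_CATEGORIES <- c("BP", "CC", "MF", "PATHWAY", "DISEASE")

#' Derive a deterministic sub-seed for a named random stream
#'
#' One root seed feeds independent, named sub-streams (one per generated
#' table), so adding a generator stage never perturbs the draws of earlier
#' stages. The sub-seed is a stable hash of the root seed and the stream
#' label, kept inside the 32-bit integer range.
#'
#' @param seed integer root seed.
#' @param stream character label of the stream (e.g. `"interactions"`).
#' @return A single integer seed.
#' @keywords internal
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h * 2654435.0) %% 2147483647)
}

# Stable stats::setNames replacement that tolerates zero-length input.
named <- function(x, nm) {
  names(x) <- nm
  x
}

# Uppercase gene symbols, optionally passing them through a symbol map first.
# Unmapped raw names pass through uppercased; when a map is supplied the
# unmapped names are reported once with a warning.
normalize_symbols <- function(x, symbol_map = NULL) {
  if (length(x) == 0L) return(character())
  if (is.null(symbol_map)) return(toupper(x))
  mapped <- symbol_map$official_symbol[match(x, symbol_map$raw_name)]
  miss <- is.na(mapped)
  if (any(miss)) {
    warn(sprintf(
      "%d raw name(s) absent from the symbol map passed through uppercased: %s",
      sum(miss), paste(unique(x[miss]), collapse = ", ")
    ))
    mapped[miss] <- toupper(x[miss])
  }
  mapped
}

#' Read a raw-name to official-symbol lookup table
#'
#' A two-column tab-separated file (`raw_name`, `official_symbol`) standing in
#' for the manual UniProt-based correction of protein names to official gene
#' symbols. The mapping must be a function: each raw name maps to exactly one
#' symbol. Official symbols are uppercased on read.
#'
#' @param path path to a TSV file with header `raw_name`, `official_symbol`.
#' @return A tibble with columns `raw_name` and `official_symbol`.
#' @export
read_symbol_map <- function(path) {
  df <- read_tsv_strict(path, c("raw_name", "official_symbol"))
  if (anyDuplicated(df$raw_name)) {
    dups <- unique(df$raw_name[duplicated(df$raw_name)])
    abort(sprintf("symbol map is not a function: raw name(s) mapped twice: %s",
                  paste(dups, collapse = ", ")))
  }
  df$official_symbol <- toupper(df$official_symbol)
  df
}

# Strict TSV reader: UTF-8, header mandatory, all columns read as character
# unless `numeric_cols` names exceptions. Missing columns raise a format
# error naming the column.
read_tsv_strict <- function(path, required, numeric_cols = character()) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  as_tibble(df[required])
}

# Write a tibble as a plain TSV (UTF-8, header, no quoting surprises).
write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# Deterministic JSON writer used for every report and manifest: stable key
# order is the caller's responsibility; values are written unboxed at full
# precision so re-runs are byte-comparable.
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
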