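#' Canonicalize a scored protein-protein edge table
#'
#' Edges are undirected: endpoints are stored in lexicographic order so the
#' unordered pair is the key. Duplicate pairs keep the maximum combined score
#' (a conservative, deterministic resolution). Self-interactions are dropped
#' with a warning; scores must lie in \[0, 1\].
#'
#' @param df tibble with columns `protein_a`, `protein_b`, `combined_score`.
#' @return The canonicalized tibble, sorted by endpoints.
#' @export
scored_edges <- function(df) {
  stopifnot(all(c("protein_a", "protein_b", "combined_score") %in% names(df)))
  df <- as_tibble(df[c("protein_a", "protein_b", "combined_score")])
  df$combined_score <- as.numeric(df$combined_score)
  if (nrow(df) == 0L) return(df)
  if (any(df$combined_score < 0 | df$combined_score > 1 | is.na(df$combined_score))) {
    abort("combined_score values must lie in [0, 1]")
  }
  self <- df$protein_a == df$protein_b
  if (any(self)) {
    warn(sprintf("%d self-interaction(s) dropped", sum(self)))
    df <- df[!self, ]
  }
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- a
  df$protein_b <- b
  df <- dplyr::summarise(df, combined_score = max(.data$combined_score),
                         .by = c("protein_a", "protein_b"))
  dplyr::arrange(df, .data$protein_a, .data$protein_b)
}

#' Read a STRING-style scored edge table from TSV
#'
#' Three mandatory columns: `protein_a`, `protein_b`, `combined_score`. Both
#' score dialects found in STRING exports are accepted: real scores in
#' \[0, 1\], or the 0-999 integer scale, which is auto-detected (any score
#' above 1) and divided by 1000 with a message. Pairs are canonicalized and
#' duplicates keep the maximum score (see [scored_edges()]).
#'
#' @param path path to a tab-separated file.
#' @return A canonicalized scored-edge tibble.
#' @export
read_scored_edges <- function(path) {
  df <- read_tsv_strict(path, c("protein_a", "protein_b", "combined_score"),
                        numeric_cols = "combined_score")
  if (nrow(df) > 0L && any(is.na(df$combined_score))) {
    abort(sprintf("'%s': unparseable combined_score value", path))
  }
  if (nrow(df) > 0L && any(df$combined_score > 1)) {
    if (any(df$combined_score > 999 | df$combined_score < 0)) {
      abort(sprintf("'%s': scores outside both the [0,1] and 0-999 dialects", path))
    }
    inform(sprintf("'%s': integer-scale scores detected; dividing by 1000", path))
    df$combined_score <- df$combined_score / 1000
  }
  scored_edges(df)
}

#' Write a scored edge table to TSV
#'
#' @param df a scored-edge tibble.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_scored_edges <- function(df, path) {
  write_tsv_plain(scored_edges(df), path)
}
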