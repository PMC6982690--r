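#' Construct a gene-set collection
#'
#' The container for named gene sets used throughout the pipeline: disease
#' gene sets (category `DISEASE`), pathway annotation sets (`PATHWAY`), and
#' GO-style ontology sets (`BP`, `CC`, `MF`). Annotations are flat sets; no
#' ontology topology is represented. An optional background universe can be
#' attached and is consulted at enrichment time.
#'
#' @param set_id character vector of unique set identifiers.
#' @param description character vector of free-text descriptions.
#' @param category character vector; each element one of
#'   `r paste0('"', GENESET_CATEGORIES, '"', collapse = ", ")`.
#' @param members list of character vectors of gene symbols; duplicates within
#'   a set are collapsed.
#' @param background optional character vector of gene symbols.
#' @return A tibble with columns `set_id`, `description`, `category`,
#'   `members` (list column) and a `background` attribute.
#' @export
gene_set_collection <- function(set_id = character(), description = character(),
                                category = character(), members = list(),
                                background = NULL) {
  tbl <- tibble(set_id = as.character(set_id),
                description = as.character(description),
                category = as.character(category),
                members = lapply(members, function(m) unique(as.character(m))))
  validate_gene_set_collection(tbl, background)
}

validate_gene_set_collection <- function(tbl, background = NULL) {
  stopifnot(all(c("set_id", "description", "category", "members") %in% names(tbl)))
  if (anyDuplicated(tbl$set_id)) abort("gene set ids must be unique")
  bad <- setdiff(unique(tbl$category), GENESET_CATEGORIES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown gene-set category: %s (expected one of %s)",
                  paste(bad, collapse = ", "),
                  paste(GENESET_CATEGORIES, collapse = ", ")))
  }
  out <- as_tibble(tbl)
  attr(out, "background") <- if (is.null(background)) NULL else
    unique(as.character(background))
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line in the Broad convention:
#' `set_id TAB description TAB member1 TAB member2 ...`. Members are
#' uppercased (through a symbol map when one is supplied) and duplicates
#' within a line are collapsed. Lines with fewer than three fields raise a
#' format error naming the line.
#'
#' @param path path to a GMT file.
#' @param category category label applied to every set in the file (GMT does
#'   not carry one); defaults to `"PATHWAY"`.
#' @param symbol_map optional symbol map tibble.
#' @return A gene-set collection (see [gene_set_collection()]).
#' @export
read_gmt <- function(path, category = "PATHWAY", symbol_map = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_set_collection(category = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("'%s': line %d has fewer than 3 tab-separated fields",
                  path, short[1L]))
  }
  gene_set_collection(
    set_id = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    category = rep(category, length(fields)),
    members = lapply(fields, function(f) {
      unique(normalize_symbols(f[-(1:2)], symbol_map))
    })
  )
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a gene-set collection.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  validate_gene_set_collection(collection)
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$description[i],
            collection$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
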