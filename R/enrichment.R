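#' Exact hypergeometric upper-tail probability
#'
#' The over-representation p-value: the probability of drawing at least `k`
#' annotated genes when `n` genes are drawn without replacement from a
#' background of `N` genes of which `K` are annotated,
#' \deqn{P[X \ge k] = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.}
#' The sum is accumulated in log space (log-binomials plus log-sum-exp) so
#' large backgrounds do not overflow or lose the tail to cancellation.
#'
#' @param k observed hit count (`0 <= k <= min(K, n)`).
#' @param K annotated genes in the background.
#' @param n query size.
#' @param N background size.
#' @return The exact tail probability, a number in \[0, 1\].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || any(c(k, K, n, N) != floor(c(k, K, n, N)))) {
    abort("hypergeom_tail arguments must be non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) {
    abort(sprintf("hypergeom_tail bounds violated: k=%d K=%d n=%d N=%d", k, K, n, N))
  }
  if (k == 0L) return(1)
  hi <- min(K, n)
  lo <- max(k, n - (N - K))   # support lower bound: n - i <= N - K
  i <- lo:hi
  lw <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lw)
  min(1, exp(m + log(sum(exp(lw - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control
#' (`q_i = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in the input
#' order), delegated to [stats::p.adjust()] after a domain check. The
#' adjustment is idempotent and monotone non-decreasing along the sorted
#' p-value order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list against a set collection
#'
#' For each gene set whose background-restricted size `K` lies within
#' `[min_size, max_size]`, the exact hypergeometric tail of the overlap with
#' the query is computed, p-values are BH-adjusted across the tested sets,
#' and results significant at `alpha` (strict `<`) are returned sorted by raw
#' p-value then set id. The background defaults to the union of all
#' collection members and must cover the query; set members outside the
#' background are ignored when counting.
#'
#' @param query character vector of gene symbols (the potential-target list).
#' @param collection a gene-set collection.
#' @param background optional character vector; defaults to the union of
#'   collection members (or the collection's `background` attribute when set).
#' @param alpha significance level (default 0.05).
#' @param filter_on `"p_adj"` (default) or `"p_raw"`: which p-value the
#'   `alpha` filter applies to.
#' @param min_size,max_size eligible background-restricted set sizes
#'   (defaults 3 and 500).
#' @return A tibble with columns `set_id`, `category`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_adj`, `hits` (list column).
#' @export
run_ora <- function(query, collection, background = NULL, alpha = 0.05,
                    filter_on = c("p_adj", "p_raw"), min_size = 3L,
                    max_size = 500L) {
  filter_on <- match.arg(filter_on)
  collection <- validate_gene_set_collection(collection,
                                             attr(collection, "background"))
  if (is.null(background)) background <- attr(collection, "background")
  if (is.null(background)) background <- unique(unlist(collection$members))
  background <- unique(as.character(background))
  if (length(background) == 0L) {
    abort("enrichment background is empty: supply a background universe")
  }
  query <- unique(as.character(query))
  offenders <- setdiff(query, background)
  if (length(offenders) > 0L) {
    abort(sprintf("query gene(s) absent from the background: %s",
                  paste(offenders, collapse = ", ")))
  }
  empty <- tibble(set_id = character(), category = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_raw = numeric(), p_adj = numeric(), hits = list())
  if (length(query) == 0L || nrow(collection) == 0L) return(empty)

  N <- length(background)
  n <- length(query)
  members_bg <- lapply(collection$members, intersect, background)
  K <- lengths(members_bg)
  eligible <- K >= min_size & K <= max_size
  if (!any(eligible)) return(empty)
  idx <- which(eligible)
  hits <- lapply(members_bg[idx], intersect, query)
  k <- lengths(hits)
  p_raw <- vapply(seq_along(idx), function(j) {
    hypergeom_tail(k[j], K[idx[j]], n, N)
  }, numeric(1))
  res <- tibble(set_id = collection$set_id[idx],
                category = collection$category[idx],
                k = as.integer(k), K = as.integer(K[idx]),
                n = as.integer(n), N = as.integer(N),
                p_raw = p_raw, p_adj = bh_adjust(p_raw),
                hits = lapply(hits, sort))
  # strict "<" per the P < 0.05 convention; alpha = 1 disables the filter so
  # every size-eligible set (including p = 1) is reported
  p_filter <- if (filter_on == "p_adj") res$p_adj else res$p_raw
  keep <- if (alpha >= 1) rep(TRUE, nrow(res)) else p_filter < alpha
  dplyr::arrange(res[keep, ], .data$p_raw, .data$set_id)
}

#' Truncate enrichment results to per-category limits
#'
#' Keeps at most the stated number of best-p terms per category (e.g. 30
#' biological-process, 30 cellular-component, and 25 molecular-function GO
#' terms), preserving the raw-p order with ties broken by set id. Categories
#' without a stated limit are returned in full.
#'
#' @param results an enrichment result tibble from [run_ora()].
#' @param per_category_limits named integer vector, e.g.
#'   `c(BP = 30, CC = 30, MF = 25)`.
#' @return The truncated result tibble, in the input order.
#' @export
top_terms <- function(results, per_category_limits) {
  stopifnot(all(c("set_id", "category", "p_raw") %in% names(results)))
  results <- dplyr::arrange(results, .data$p_raw, .data$set_id)
  keep <- unlist(lapply(split(seq_len(nrow(results)), results$category),
                        function(rows) {
    cat_label <- results$category[rows[1L]]
    lim <- per_category_limits[cat_label]
    if (is.na(lim)) rows else utils::head(rows, lim)
  }))
  results[sort(keep), ]
}
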