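# Independent oracles used to cross-check the package's computations.
# They share no algorithmic code with the implementation: centralities come
# from a plain BFS with explicit path counting, and hypergeometric tails
# from exhaustive enumeration of draws.

# All-pairs BFS distances and shortest-path counts from adjacency lists.
oracle_sp <- function(ids, el) {
  n <- length(ids)
  adj <- setNames(rep(list(character()), n), ids)
  if (nrow(el) > 0L) {
    for (r in seq_len(nrow(el))) {
      adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
      adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
    }
  }
  dist <- matrix(Inf, n, n, dimnames = list(ids, ids))
  sigma <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in ids) {
    d <- setNames(rep(Inf, n), ids)
    sg <- setNames(rep(0, n), ids)
    d[s] <- 0
    sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- character()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- union(nxt, w)
          }
          if (d[w] == d[v] + 1) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- nxt
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  list(dist = dist, sigma = sigma)
}

# Normalized DC/BC/CC by exhaustive shortest-path enumeration.
oracle_centralities <- function(net) {
  ids <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = TRUE)
  if (length(ids) == 0L) {
    return(data.frame(node_id = character(), DC = integer(),
                      BC = numeric(), CC = numeric()))
  }
  sp <- oracle_sp(ids, el)
  n <- length(ids)
  dc <- integer(n)
  if (nrow(el) > 0L) {
    tab <- table(c(el[, 1], el[, 2]))
    dc <- as.integer(tab[ids])
    dc[is.na(dc)] <- 0L
  }
  bc <- setNames(rep(0, n), ids)
  for (si in seq_len(n)) {
    for (ti in seq_len(n)) {
      if (si < ti && is.finite(sp$dist[si, ti])) {
        on_path <- is.finite(sp$dist[si, ]) & is.finite(sp$dist[, ti]) &
          (sp$dist[si, ] + sp$dist[, ti] == sp$dist[si, ti])
        on_path[c(si, ti)] <- FALSE
        bc[on_path] <- bc[on_path] +
          sp$sigma[si, on_path] * sp$sigma[on_path, ti] / sp$sigma[si, ti]
      }
    }
  }
  reach <- rowSums(is.finite(sp$dist)) - 1
  sumd <- vapply(seq_len(n), function(i) {
    d <- sp$dist[i, ]
    sum(d[is.finite(d) & d > 0])
  }, numeric(1))
  nc <- reach + 1
  data.frame(
    node_id = ids,
    DC = dc,
    BC = ifelse(nc >= 3, bc / ((nc - 1) * (nc - 2) / 2), 0),
    CC = ifelse(reach > 0, reach / sumd, 0),
    stringsAsFactors = FALSE
  )
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
# from a population whose first K items are annotated.
oracle_hypergeom <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Random role-typed test network on up to `max_n` nodes.
random_network <- function(max_n = 30, p = NULL) {
  n <- sample(2:max_n, 1)
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.4)
  g <- igraph::sample_gnp(n, p)
  ids <- sprintf("n%02d", seq_len(n))
  el <- igraph::as_edgelist(g)
  hn_network(
    tibble::tibble(id = ids, role = sample(c("protein", "target"), n, TRUE)),
    tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]])
  )
}

# Random gene-set collection over a small universe.
random_collection <- function(n_sets = 5, universe = sprintf("G%03d", 1:40)) {
  gene_set_collection(
    set_id = sprintf("S%02d", seq_len(n_sets)),
    description = sprintf("random set %d", seq_len(n_sets)),
    category = sample(c("PATHWAY", "BP", "CC", "MF"), n_sets, TRUE),
    members = lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(3:12, 1))
    })
  )
}
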