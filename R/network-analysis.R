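#' Build the compound-target-disease network
#'
#' A tripartite undirected graph: active compounds link to the potential
#' targets they hit, and each potential target links to every disease gene
#' set containing it. Disease nodes connect to targets, never directly to
#' compounds. By construction of the active set no node is isolated.
#'
#' @param active an `active_set` from [map_to_diseases()].
#' @param compound_targets the named list from [attach_targets()].
#' @return An [hn_network()] with roles `compound`, `target`, `disease`.
#' @export
build_ctd <- function(active, compound_targets) {
  stopifnot(inherits(active, "active_set"))
  diseases <- sort(unique(unlist(active$target_to_diseases)))
  nodes <- tibble(
    id = c(active$active_compounds, active$potential_targets, diseases),
    role = rep(c("compound", "target", "disease"),
               c(length(active$active_compounds),
                 length(active$potential_targets), length(diseases)))
  )
  no_edges <- tibble(from = character(), to = character())
  ct <- dplyr::bind_rows(no_edges, lapply(active$active_compounds, function(cid) {
    tg <- intersect(compound_targets[[cid]], active$potential_targets)
    tibble(from = rep(cid, length(tg)), to = tg)
  }))
  td <- dplyr::bind_rows(no_edges, lapply(active$potential_targets, function(t) {
    ds <- active$target_to_diseases[[t]]
    tibble(from = rep(t, length(ds)), to = ds)
  }))
  hn_network(nodes, dplyr::bind_rows(ct, td))
}

#' Build the target-pathway network
#'
#' A bipartite graph over the screened targets and the selected pathways:
#' an edge records pathway membership, so each pathway node's degree equals
#' the size of its member set intersected with the potential-target list.
#' Targets annotated to none of the selected pathways are omitted; selected
#' pathways are always included as nodes.
#'
#' @param potential_targets character vector of gene symbols.
#' @param pathways a gene-set collection holding the pathway annotations.
#' @param selected_pathways character vector of set ids to include; must all
#'   exist in the collection.
#' @return An [hn_network()] with roles `target`, `pathway`.
#' @export
build_tp <- function(potential_targets, pathways, selected_pathways) {
  pathways <- validate_gene_set_collection(pathways, attr(pathways, "background"))
  unknown <- setdiff(selected_pathways, pathways$set_id)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown pathway id(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(selected_pathways) == 0L) {
    return(hn_network(tibble(id = character(), role = character())))
  }
  idx <- match(selected_pathways, pathways$set_id)
  edges <- dplyr::bind_rows(tibble(from = character(), to = character()),
                            lapply(idx, function(i) {
    tg <- intersect(pathways$members[[i]], potential_targets)
    tibble(from = rep(pathways$set_id[i], length(tg)), to = tg)
  }))
  targets <- sort(unique(edges$to))
  nodes <- tibble(
    id = c(targets, pathways$set_id[idx]),
    role = rep(c("target", "pathway"), c(length(targets), length(idx)))
  )
  hn_network(nodes, edges)
}

#' Build the protein-protein interaction network
#'
#' Keeps scored edges whose endpoints both belong to the node subset and
#' whose combined confidence score is strictly greater than the threshold
#' (the STRING-style `> 0.4` medium-confidence cut). All subset members are
#' retained as protein nodes; members left without any passing edge are
#' flagged with the `isolated` vertex attribute.
#'
#' @param edges a canonicalized scored-edge tibble (see [scored_edges()]).
#' @param node_subset character vector of gene symbols.
#' @param threshold confidence cutoff in \[0, 1\]; default 0.4.
#' @return An [hn_network()] of role `protein`.
#' @export
build_ppi <- function(edges, node_subset, threshold = 0.4) {
  stopifnot(threshold >= 0, threshold <= 1)
  edges <- scored_edges(edges)
  node_subset <- unique(as.character(node_subset))
  keep <- edges$protein_a %in% node_subset & edges$protein_b %in% node_subset &
    edges$combined_score > threshold
  kept <- edges[keep, ]
  nodes <- tibble(id = sort(node_subset), role = "protein")
  net <- hn_network(nodes, tibble(from = kept$protein_a, to = kept$protein_b))
  igraph::V(net)$isolated <- igraph::degree(net) == 0L
  net
}

#' Degree, betweenness, and closeness centrality of every node
#'
#' The three screening centralities, computed on unweighted shortest paths:
#' * `DC` — raw degree, the number of incident edges.
#' * `BC` — betweenness: the sum over node pairs of the fraction of shortest
#'   paths passing through the node, normalized by the number of pairs in the
#'   node's connected component, `(Nc - 1)(Nc - 2) / 2` (0 when the component
#'   has fewer than 3 nodes).
#' * `CC` — closeness: the number of reachable nodes divided by the sum of
#'   distances to them (0 for isolated nodes).
#'
#' Both BC and CC are computed within connected components; cross-component
#' pairs contribute nothing. These are the normalizations that place values
#' in \[0, 1\] and match common network-viewer output on disconnected
#' graphs. `normalized = FALSE` exposes the raw quantities instead
#' (pair-dependency sums for BC, reciprocal summed distance for CC).
#'
#' @param net an [hn_network()].
#' @param normalized logical; default `TRUE`.
#' @return A tibble with columns `node_id`, `role`, `DC`, `BC`, `CC`, in
#'   vertex order.
#' @export
compute_centralities <- function(net, normalized = TRUE) {
  nv <- igraph::vcount(net)
  out <- tibble(node_id = igraph::V(net)$name, role = igraph::V(net)$role,
                DC = as.integer(igraph::degree(net)),
                BC = numeric(nv), CC = numeric(nv))
  if (nv == 0L) return(out)
  comp <- igraph::components(net)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    nc <- length(members)
    if (nc == 1L) next  # BC = CC = 0 for isolated nodes
    sub <- igraph::induced_subgraph(net, members)
    ord <- match(igraph::V(sub)$name, out$node_id)
    bc <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    d <- igraph::distances(sub)
    sumd <- rowSums(d)
    if (normalized) {
      out$BC[ord] <- if (nc < 3L) 0 else bc / ((nc - 1) * (nc - 2) / 2)
      out$CC[ord] <- (nc - 1) / sumd
    } else {
      out$BC[ord] <- bc
      out$CC[ord] <- 1 / sumd
    }
  }
  out
}

#' Mean centralities over one node role
#'
#' The screening baselines: arithmetic means of DC, BC, and CC over all
#' records of the given role, at full precision (rounding belongs to display
#' layers only).
#'
#' @param records a centrality tibble from [compute_centralities()].
#' @param role one of `r paste0('"', NODE_ROLES, '"', collapse = ", ")`.
#' @return A named list with `mean_DC`, `mean_BC`, `mean_CC`.
#' @export
role_averages <- function(records, role) {
  rows <- records[records$role == role, ]
  if (nrow(rows) == 0L) {
    abort(sprintf("no centrality records with role '%s'", role))
  }
  list(mean_DC = mean(rows$DC), mean_BC = mean(rows$BC), mean_CC = mean(rows$CC))
}

#' Screen key compounds by the triple-above-average rule
#'
#' A compound is key when all three of its centralities strictly exceed the
#' corresponding means over the compound nodes of the same network (strict
#' `>`: a network of identical compounds yields no key compound). Thresholds
#' default to [role_averages()] over the stated role and may be supplied
#' explicitly.
#'
#' @param records a centrality tibble.
#' @param thresholds optional list with `mean_DC`, `mean_BC`, `mean_CC`.
#' @param role role over which default thresholds are computed and screening
#'   applies; default `"compound"`.
#' @return The selected rows, sorted by DC then BC descending, then node id.
#' @export
screen_key_compounds <- function(records, thresholds = NULL, role = "compound") {
  if (is.null(thresholds)) thresholds <- role_averages(records, role)
  rows <- records[records$role == role, ]
  sel <- rows$DC > thresholds$mean_DC & rows$BC > thresholds$mean_BC &
    rows$CC > thresholds$mean_CC
  dplyr::arrange(rows[sel, ], dplyr::desc(.data$DC), dplyr::desc(.data$BC),
                 .data$node_id)
}

#' Select hub nodes by degree above the network mean
#'
#' The hub-gene rule for the protein-protein interaction network: a node is a
#' hub when its degree strictly exceeds the mean degree over all nodes of the
#' network. On any regular graph the selection is empty.
#'
#' @param records a centrality tibble (all nodes of one network).
#' @return The selected rows, sorted by DC descending then node id.
#' @export
select_hub_nodes <- function(records) {
  if (nrow(records) == 0L) return(records)
  sel <- records$DC > mean(records$DC)
  dplyr::arrange(records[sel, ], dplyr::desc(.data$DC), .data$node_id)
}

#' Select key pathways
#'
#' Two rules are available. The default `"centrality"` rule mirrors the
#' key-compound screen on pathway nodes: all three centralities must strictly
#' exceed the means over pathway nodes (a single pathway can never exceed its
#' own mean). The `"explicit"` rule returns a configured id list verbatim —
#' the escape hatch for literature-informed selections that no centrality
#' rule reproduces.
#'
#' @param records a centrality tibble from the target-pathway network.
#' @param rule `"centrality"` (default) or `"explicit"`.
#' @param ids character vector of pathway set ids, required by the
#'   `"explicit"` rule.
#' @return A character vector of pathway set ids.
#' @export
select_key_pathways <- function(records, rule = c("centrality", "explicit"),
                                ids = NULL) {
  rule <- tryCatch(match.arg(rule),
                   error = function(e) abort(sprintf(
                     "unknown key-pathway rule '%s' (use \"centrality\" or \"explicit\")",
                     rule[1])))
  if (rule == "explicit") {
    if (is.null(ids)) abort("the explicit rule requires a pathway id list")
    return(as.character(ids))
  }
  screen_key_compounds(records, role = "pathway")$node_id
}
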