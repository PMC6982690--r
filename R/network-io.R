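#' Construct a role-typed undirected network
#'
#' All three pipeline networks (compound-target-disease, target-pathway,
#' protein-protein interaction) share one representation: a simple undirected
#' igraph whose vertices carry a `role` attribute, one of
#' `r paste0('"', NODE_ROLES, '"', collapse = ", ")`. Node identifiers are
#' unique across roles; self-loops are rejected and duplicate edges collapse.
#'
#' @param nodes tibble with columns `id`, `role`.
#' @param edges tibble with columns `from`, `to` (node ids); may be empty.
#' @return An undirected igraph with vertex attributes `name` and `role`.
#' @export
hn_network <- function(nodes, edges = tibble(from = character(), to = character())) {
  stopifnot(all(c("id", "role") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes$id)) abort("node ids must be unique across roles")
  bad <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown node role: %s", paste(bad, collapse = ", ")))
  }
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    undeclared <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(undeclared) > 0L) {
      abort(sprintf("edge endpoint(s) not declared as nodes: %s",
                    paste(undeclared, collapse = ", ")))
    }
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- tibble(from = a[keep], to = b[keep])
  }
  igraph::graph_from_data_frame(
    d = as.data.frame(edges),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, role = nodes$role,
                          stringsAsFactors = FALSE)
  )
}

# Tibble views of an hn_network, used by writers and reports.
network_nodes <- function(net) {
  tibble(id = igraph::V(net)$name, role = igraph::V(net)$role)
}

network_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]))
}

#' Write a network to SIF or GraphML
#'
#' SIF lines are `a <relation> b` with the relation naming the role pair
#' (e.g. `compound-target`); isolated nodes are written as bare single-token
#' lines, the standard SIF convention. GraphML (written through igraph)
#' carries the `role` vertex attribute, so re-reading a GraphML file
#' reproduces the node set, edge set, and roles exactly; SIF is a lossier
#' Cytoscape-interchange export (roles of isolated nodes are not encoded).
#'
#' @param net an [hn_network()].
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf(
                       "unknown network format '%s' (use \"sif\" or \"graphml\")",
                       format[1])))
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  role_of <- named(nodes$role, nodes$id)
  lines <- character()
  if (nrow(edges) > 0L) {
    lines <- sprintf("%s %s-%s %s", edges$from, role_of[edges$from],
                     role_of[edges$to], edges$to)
  }
  isolated <- setdiff(nodes$id, unique(c(edges$from, edges$to)))
  writeLines(c(lines, isolated), path, useBytes = TRUE)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input path.
#' @param format `"sif"` or `"graphml"`.
#' @return An [hn_network()].
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf(
                       "unknown network format '%s' (use \"sif\" or \"graphml\")",
                       format[1])))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ids <- igraph::V(g)$name
    roles <- igraph::V(g)$role
    el <- igraph::as_edgelist(g, names = TRUE)
    return(hn_network(
      tibble(id = if (is.null(ids)) character() else ids,
             role = if (is.null(roles)) character() else roles),
      tibble(from = as.character(el[, 1]), to = as.character(el[, 2]))
    ))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  is_edge <- lengths(parts) == 3L
  nodes <- list()
  edges <- tibble(from = character(), to = character())
  if (any(is_edge)) {
    ep <- do.call(rbind, parts[is_edge])
    roles <- strsplit(ep[, 2], "-", fixed = TRUE)
    nodes <- tibble(
      id = c(ep[, 1], ep[, 3]),
      role = c(vapply(roles, `[[`, "", 1L), vapply(roles, `[[`, "", 2L))
    )
    edges <- tibble(from = ep[, 1], to = ep[, 3])
  }
  lone <- unlist(parts[!is_edge])
  all_nodes <- dplyr::distinct(dplyr::bind_rows(
    if (length(nodes)) nodes else tibble(id = character(), role = character()),
    tibble(id = setdiff(lone, if (length(nodes)) nodes$id else character()),
           role = "protein")
  ), .data$id, .keep_all = TRUE)
  hn_network(all_nodes, edges)
}
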