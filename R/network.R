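## Interaction subnetwork of selected genes, degrees, and hub calling.

#' Induced interaction subnetwork of selected genes
#'
#' Restricts the background interaction graph to the selected genes present
#' in it. Selected genes with no selected interaction partner are retained
#' as degree-0 nodes; selected genes absent from the background graph are
#' dropped.
#'
#' @param selected_genes Character vector of gene symbols.
#' @param graph Undirected [igraph::igraph] background graph with a `name`
#'   vertex attribute.
#' @return The induced [igraph::igraph] subgraph.
#' @export
build_subnetwork <- function(selected_genes, graph) {
  stopifnot(inherits(graph, "igraph"))
  nodes <- intersect(toupper(selected_genes), igraph::V(graph)$name)
  igraph::induced_subgraph(graph, nodes)
}

#' Node degrees of an interaction graph
#'
#' The degree of a protein is its number of distinct interaction partners
#' (self-loops never count).
#'
#' @param graph Undirected [igraph::igraph] graph.
#' @return Named integer vector of degrees.
#' @export
compute_degrees <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  d <- igraph::degree(g)
  stats::setNames(as.integer(d), igraph::V(g)$name)
}

#' Call hub molecules from a degree map
#'
#' Hubs are nodes whose degree meets the cutoff; the boundary is inclusive
#' by default (degree == cutoff qualifies), with `strict = TRUE` for the
#' exclusive reading. Hubs are ordered by descending degree, ties broken
#' lexicographically.
#'
#' @param degrees Named integer vector from [compute_degrees()].
#' @param cutoff Minimum degree (default 10).
#' @param strict If TRUE require degree > cutoff instead of >=.
#' @return data.frame with `gene` and `degree`, one row per hub.
#' @export
select_hubs <- function(degrees, cutoff = 10L, strict = FALSE) {
  cutoff <- check_positive_int(cutoff, "cutoff")
  keep <- if (strict) degrees > cutoff else degrees >= cutoff
  hubs <- degrees[keep]
  ord <- order(-hubs, names(hubs))
  data.frame(gene = names(hubs)[ord], degree = as.integer(hubs[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate a subnetwork with degree and regulation direction
#'
#' Adds `degree` and (when a selection table is supplied) `direction` vertex
#' attributes, so that GraphML exports carry the information needed for
#' downstream up/down coloring.
#'
#' @param graph Undirected [igraph::igraph] graph.
#' @param vip_table Optional [select_genes()] table carrying `gene` and
#'   `direction` columns.
#' @return The graph with vertex attributes set.
#' @export
annotate_network <- function(graph, vip_table = NULL) {
  deg <- compute_degrees(graph)
  graph <- igraph::set_vertex_attr(graph, "degree",
                                   value = deg[igraph::V(graph)$name])
  if (!is.null(vip_table) && !is.null(vip_table$gene)) {
    sel <- vip_table[vip_table$selected & !is.na(vip_table$gene), , drop = FALSE]
    dir_map <- tapply(sel$direction, sel$gene, function(d) d[[1L]])
    dirs <- unname(dir_map[igraph::V(graph)$name])
    dirs[is.na(dirs)] <- "unknown"
    graph <- igraph::set_vertex_attr(graph, "direction", value = dirs)
  }
  graph
}
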