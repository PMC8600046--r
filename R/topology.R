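#' Topology report of an interaction network
#'
#' Computes, on the simple undirected graph (self-loops excluded), the
#' node-level and graph-level parameters used by the Cytoscape
#' NetworkAnalyzer tool: per node, degree and normalized betweenness
#' centrality; per graph, the average clustering coefficient (nodes of
#' degree < 2 count as 0), number of connected components, Freeman degree
#' centralization, average number of neighbors, node count, density,
#' heterogeneity (sd(degree)/mean(degree)) and isolated-node count.
#'
#' Betweenness is normalized by `2 / ((n - 1)(n - 2))` with `n` the size
#' of the node's connected component, reproducing the 0-1 values that
#' tool prints; for disconnected graphs this component-wise normalization
#' is flagged in the report.
#'
#' @param net An `interactome` or igraph graph; must be non-empty.
#' @return A `topology_report`: list with `nodes` (tibble `protein`,
#'   `degree`, `betweenness`) and `graph` (one-row tibble of graph-level
#'   parameters). Use [tidy()] / [glance()] to extract them.
#' @examples
#' net <- assemble_interactome(data.frame(protein_a = c("A", "B"),
#'                                        protein_b = c("B", "C")), NULL)
#' glance(topology_report(net))
#' @export
topology_report <- function(net) {
  if (igraph::vcount(net) == 0) {
    abort("cannot compute topology of an empty graph",
          class = "peroxnet_empty_graph")
  }
  sg <- simple_graph(net)
  comp <- igraph::components(sg)
  deg <- igraph::degree(sg)
  n <- igraph::vcount(sg)

  # component-wise normalized betweenness
  btw_raw <- igraph::betweenness(sg, directed = FALSE, normalized = FALSE)
  csize <- comp$csize[comp$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(denom > 0, btw_raw / denom, 0)

  local_cc <- igraph::transitivity(sg, type = "localundirected",
                                   isolates = "zero")
  density <- igraph::edge_density(sg)
  centralization <- igraph::centr_degree(sg, loops = FALSE)$centralization
  nodes <- tibble(protein = igraph::V(sg)$name, degree = deg,
                  betweenness = btw) |>
    arrange(dplyr::desc(.data$betweenness))
  graph <- tibble(
    n_nodes = as.integer(n),
    n_edges = as.integer(igraph::ecount(sg)),
    avg_clustering = mean(local_cc),
    n_components = as.integer(comp$no),
    degree_centralization = centralization,
    avg_neighbors = mean(deg),
    density = if (is.nan(density)) 0 else density,
    heterogeneity = if (mean(deg) > 0) sd(deg) / mean(deg) else 0,
    n_isolated = sum(deg == 0),
    componentwise_normalization = comp$no > 1)
  structure(list(nodes = nodes, graph = graph), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>", x$graph$n_nodes, "nodes,", x$graph$n_edges, "edges,",
      x$graph$n_components, "component(s)\n")
  cat(sprintf("  avg clustering %.3f | density %.3f | heterogeneity %.3f\n",
              x$graph$avg_clustering, x$graph$density, x$graph$heterogeneity))
  print(head(x$nodes, 5))
  invisible(x)
}

#' @rdname topology_report
#' @param x A `topology_report`.
#' @param ... Unused.
#' @export
tidy.topology_report <- function(x, ...) x$nodes

#' @rdname topology_report
#' @export
glance.topology_report <- function(x, ...) x$graph

#' Model removal of a node from the network
#'
#' Deletes a protein (and optionally a set of functionally excluded
#' proteins, e.g. chaperones not part of the organelle's intrinsic
#' function) and reports the topological consequences: the before/after
#' reports, newly isolated nodes, and the component-count change.
#'
#' @param net An `interactome`.
#' @param node Protein to remove.
#' @param exclude Optional additional proteins removed together with
#'   `node` (functional weighting).
#' @return A `node_removal` object: list with `before`, `after`
#'   ([topology_report()]s), `removed`, `isolated` (proteins isolated by
#'   the removal) and `components_delta`.
#' @export
remove_node_analysis <- function(net, node, exclude = NULL) {
  node <- norm_symbol(node)
  if (!node %in% igraph::V(net)$name) {
    abort(paste0("node not in network: ", node),
          class = "peroxnet_missing_node")
  }
  removed <- unique(c(node, if (!is.null(exclude)) norm_symbol(exclude)))
  before <- topology_report(net)
  after_g <- igraph::delete_vertices(net, intersect(removed, igraph::V(net)$name))
  class(after_g) <- c("interactome", class(after_g))
  after <- topology_report(after_g)
  was_connected <- before$nodes |> filter(.data$degree > 0) |> pull("protein")
  now_isolated <- after$nodes |> filter(.data$degree == 0) |> pull("protein")
  structure(
    list(before = before, after = after, removed = removed,
         isolated = intersect(was_connected, now_isolated),
         components_delta = after$graph$n_components - before$graph$n_components),
    class = "node_removal")
}

#' @export
print.node_removal <- function(x, ...) {
  cat("<node_removal> removed:", paste(x$removed, collapse = ", "), "\n")
  cat("  components:", x$before$graph$n_components, "->",
      x$after$graph$n_components, "| newly isolated:",
      if (length(x$isolated)) paste(x$isolated, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @rdname remove_node_analysis
#' @param x A `node_removal`.
#' @param ... Unused.
#' @export
glance.node_removal <- function(x, ...) {
  tibble(removed = paste(x$removed, collapse = "+"),
         components_before = x$before$graph$n_components,
         components_after = x$after$graph$n_components,
         components_delta = x$components_delta,
         n_isolated_new = length(x$isolated))
}
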