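#' Disease-disease edges from shared genes
#'
#' Two clinical phenotypes are linked when they share at least one
#' associated gene. Edges are unweighted; the shared-gene count is kept
#' as an attribute column.
#'
#' @param associations Data frame (`gene`, `phenotype`).
#' @return Tibble `phenotype_a`, `phenotype_b`, `n_shared_genes` (no
#'   self-edges, each unordered pair once).
#' @examples
#' assoc <- data.frame(gene = c("PEX26", "PEX26"), phenotype = c("ZS", "NALD"))
#' disease_disease_edges(assoc)
#' @export
disease_disease_edges <- function(associations) {
  stop_missing_cols(associations, c("gene", "phenotype"), "`associations`")
  if (nrow(associations) == 0) {
    return(tibble(phenotype_a = character(), phenotype_b = character(),
                  n_shared_genes = integer()))
  }
  a <- distinct(as_tibble(associations), .data$gene, .data$phenotype)
  inner_join(a, a, by = "gene", suffix = c("_a", "_b"),
             relationship = "many-to-many") |>
    filter(.data$phenotype_a < .data$phenotype_b) |>
    count(.data$phenotype_a, .data$phenotype_b, name = "n_shared_genes") |>
    arrange(.data$phenotype_a, .data$phenotype_b)
}

#' Build the integrated protein-disease network
#'
#' Overlays three edge layers on one heterogeneous graph: the
#' protein-protein interactions, the gene-phenotype relationships, and
#' the disease-disease links derived from shared genes. Protein and
#' disease nodes are typed; a gene symbol colliding with a disease name
#' is rejected as a type ambiguity.
#'
#' @param ppi An `interactome` (may be NULL/empty for a pure disease
#'   network).
#' @param associations Data frame (`gene`, `phenotype`).
#' @return An `integrated_network`: igraph graph with vertex attribute
#'   `type` ("protein"/"disease") and edge attribute `layer`
#'   ("ppi"/"gene_phenotype"/"disease_disease").
#' @export
build_integrated_network <- function(ppi, associations) {
  stop_missing_cols(associations, c("gene", "phenotype"), "`associations`")
  assoc <- as_tibble(associations) |>
    mutate(gene = norm_symbol(.data$gene)) |>
    distinct(.data$gene, .data$phenotype)
  ppi_edges <- if (!is.null(ppi) && igraph::ecount(ppi) > 0) {
    interactome_edges(ppi) |> select("protein_a", "protein_b")
  } else {
    tibble(protein_a = character(), protein_b = character())
  }
  proteins <- unique(c(ppi_edges$protein_a, ppi_edges$protein_b, assoc$gene))
  diseases <- unique(assoc$phenotype)
  clash <- intersect(proteins, diseases)
  if (length(clash)) {
    abort(paste0("type ambiguity: name(s) used as both gene and phenotype: ",
                 paste(clash, collapse = ", ")),
          class = "peroxnet_type_clash")
  }
  dd <- disease_disease_edges(assoc)
  edges <- bind_rows(
    ppi_edges |> rename(from = "protein_a", to = "protein_b") |>
      mutate(layer = "ppi"),
    assoc |> rename(from = "gene", to = "phenotype") |>
      mutate(layer = "gene_phenotype"),
    dd |> rename(from = "phenotype_a", to = "phenotype_b") |>
      mutate(layer = "disease_disease") |> select(-"n_shared_genes"))
  nodes <- tibble(name = c(proteins, diseases),
                  type = c(rep("protein", length(proteins)),
                           rep("disease", length(diseases))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  class(g) <- c("integrated_network", class(g))
  g
}

#' @export
print.integrated_network <- function(x, ...) {
  type <- igraph::V(x)$type
  layer <- igraph::E(x)$layer
  cat("<integrated_network>", sum(type == "protein"), "proteins +",
      sum(type == "disease"), "diseases,", igraph::ecount(x), "edges\n")
  tab <- table(layer)
  cat("  layers:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Statistics of the integrated disease network
#'
#' Computes, on the untyped undirected projection, the size of the main
#' (largest) connected component, the number of additional components,
#' the average clustering coefficient of the main component (degree < 2
#' counts 0), and the Markov-clustering modules of the main component.
#'
#' @param net An `integrated_network`.
#' @param inflation MCL inflation for module detection.
#' @return An `integrated_stats` object; [glance()] returns the one-row
#'   summary, `$modules` the module assignment of the main component.
#' @export
integrated_stats <- function(net, inflation = 2) {
  if (igraph::vcount(net) == 0) {
    abort("empty network", class = "peroxnet_empty_graph")
  }
  comp <- igraph::components(net)
  main_id <- which.max(comp$csize)
  main <- igraph::induced_subgraph(net, igraph::V(net)[comp$membership == main_id])
  cc <- igraph::transitivity(main, type = "localundirected", isolates = "zero")
  modules <- mcl_modules(main, inflation = inflation)
  structure(
    list(summary = tibble(
           n_nodes = as.integer(igraph::vcount(net)),
           n_edges = as.integer(igraph::ecount(net)),
           main_nodes = as.integer(igraph::vcount(main)),
           main_edges = as.integer(igraph::ecount(main)),
           n_additional_components = as.integer(comp$no) - 1L,
           main_avg_clustering = mean(cc),
           n_modules = max(modules$module)),
         modules = modules,
         main = main),
    class = "integrated_stats")
}

#' @export
print.integrated_stats <- function(x, ...) {
  s <- x$summary
  cat("<integrated_stats>", s$n_nodes, "nodes /", s$n_edges, "edges;",
      "main component", s$main_nodes, "/", s$main_edges, "+",
      s$n_additional_components, "further components\n")
  cat(sprintf("  main avg clustering %.3f | %d MCL modules\n",
              s$main_avg_clustering, s$n_modules))
  invisible(x)
}

#' @rdname integrated_stats
#' @param x An `integrated_stats`.
#' @param ... Unused.
#' @export
glance.integrated_stats <- function(x, ...) x$summary

#' @rdname integrated_stats
#' @export
tidy.integrated_stats <- function(x, ...) x$modules
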