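#' Assemble the merged peroxisomal interactome
#'
#' Merges interaction edges discovered in a screen with a curated set of
#' known interactions into one undirected simple graph. Symbols are
#' normalised to uppercase before merging (curated lists mix cases),
#' duplicate edges are collapsed, and an edge found in both inputs gets
#' provenance `"both"`. Self-interactions (homodimers) are retained with a
#' `self_loop` flag but are excluded from all topology metrics.
#'
#' @param novel Data frame of novel edges (`protein_a`, `protein_b`).
#' @param curated Data frame of curated known edges (same columns).
#' @return An `interactome` object (an igraph graph with `provenance` edge
#'   attribute), with tidy accessors [interactome_edges()] and
#'   [interactome_nodes()].
#' @examples
#' net <- assemble_interactome(
#'   data.frame(protein_a = "A", protein_b = "B"),
#'   data.frame(protein_a = c("b", "B"), protein_b = c("a", "C")))
#' interactome_edges(net)
#' @export
assemble_interactome <- function(novel, curated) {
  as_edges <- function(df, provenance) {
    if (is.null(df) || nrow(df) == 0) {
      return(tibble(key = character(), provenance = character()))
    }
    stop_missing_cols(df, c("protein_a", "protein_b"), "edge list")
    tibble(key = pair_key(df$protein_a, df$protein_b), provenance = provenance) |>
      distinct(.data$key, .keep_all = TRUE)
  }
  edges <- bind_rows(as_edges(novel, "novel"), as_edges(curated, "curated")) |>
    group_by(.data$key) |>
    summarise(provenance = if (n() > 1) "both" else first(.data$provenance),
              .groups = "drop") |>
    tidyr::separate_wider_delim("key", "|", names = c("protein_a", "protein_b"),
                                cols_remove = FALSE)
  g <- igraph::graph_from_data_frame(
    edges |> select("protein_a", "protein_b", "provenance", "key"),
    directed = FALSE)
  igraph::E(g)$self_loop <- igraph::which_loop(g)
  igraph::V(g)$building_block <- "unannotated"
  class(g) <- c("interactome", class(g))
  g
}

# the simple graph used by every metric: self-loops dropped
simple_graph <- function(net) {
  igraph::delete_edges(net, igraph::E(net)[igraph::which_loop(net)])
}

#' Edge table of an interactome
#' @param net An `interactome`.
#' @return Tibble `protein_a`, `protein_b`, `provenance`, `self_loop`.
#' @export
interactome_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  tibble(protein_a = el[, 1], protein_b = el[, 2],
         provenance = igraph::E(net)$provenance,
         self_loop = igraph::E(net)$self_loop)
}

#' Node table of an interactome
#' @param net An `interactome`.
#' @return Tibble `protein`, `degree` (self-loops excluded),
#'   `building_block`.
#' @export
interactome_nodes <- function(net) {
  sg <- simple_graph(net)
  tibble(protein = igraph::V(net)$name,
         degree = unname(igraph::degree(sg)),
         building_block = igraph::V(net)$building_block)
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome>", igraph::vcount(x), "proteins,", igraph::ecount(x),
      "interactions\n")
  tab <- table(igraph::E(x)$provenance)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Annotate partner nodes with functional building blocks
#'
#' Labels each protein with the peroxisomal functional group ("building
#' block") it belongs to: matrix protein import, membrane assembly,
#' division and proliferation, fatty acid metabolism, or unknown. Proteins
#' absent from the mapping keep the label `"unannotated"`.
#'
#' @param net An `interactome`.
#' @param mapping Data frame (`partner`, `block`).
#' @param required Symbols that must be covered by the mapping (default:
#'   none). Useful to insist that every screen partner is annotated.
#' @return The annotated `interactome`.
#' @export
annotate_building_blocks <- function(net, mapping, required = NULL) {
  stop_missing_cols(mapping, c("partner", "block"), "`mapping`")
  mapping <- mutate(mapping, partner = norm_symbol(.data$partner))
  if (!is.null(required)) {
    miss <- setdiff(norm_symbol(required), mapping$partner)
    if (length(miss)) {
      abort(paste0("building-block mapping missing partner(s): ",
                   paste(miss, collapse = ", ")),
            class = "peroxnet_missing_block")
    }
  }
  idx <- match(igraph::V(net)$name, mapping$partner)
  igraph::V(net)$building_block <- ifelse(is.na(idx), "unannotated",
                                          mapping$block[idx])
  net
}

#' Induced sub-network of the component containing a seed protein
#'
#' Returns the subgraph on all nodes directly or indirectly linked to the
#' seed, with every edge among them preserved.
#'
#' @param net An `interactome`.
#' @param seed Protein symbol.
#' @return An `interactome` restricted to the seed's connected component.
#' @export
induced_component <- function(net, seed) {
  seed <- norm_symbol(seed)
  if (!seed %in% igraph::V(net)$name) {
    abort(paste0("seed protein not in network: ", seed),
          class = "peroxnet_missing_node")
  }
  memb <- igraph::components(net)$membership
  sub <- igraph::induced_subgraph(net, igraph::V(net)[memb == memb[seed]])
  class(sub) <- c("interactome", class(sub))
  sub
}

#' Read a two-column edge list TSV
#' @param path TSV with columns `protein_a`, `protein_b` (extra columns kept).
#' @return Edge tibble.
#' @export
read_edges_tsv <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' Export an interactome
#'
#' `write_graphml()` uses the GraphML format; `write_sif()` the Cytoscape
#' SIF format (`protein_a <relation> protein_b`).
#'
#' @param net An `interactome` (or any igraph graph).
#' @param path Output file.
#' @param relation Interaction label used in SIF output.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_sif <- function(net, path, relation = "pp") {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], relation, el[, 2]), path)
  invisible(path)
}

#' Assemble the merged fixture interactome
#'
#' Builds the merged wild-type peroxisomal network from the packaged
#' fixtures (14 novel screen edges plus 67 curated interactions) and
#' annotates the partner building blocks.
#'
#' @param bundle A [perox_fixtures()] bundle (loaded if omitted).
#' @return The merged `interactome`.
#' @export
fixture_interactome <- function(bundle = NULL) {
  fx <- bundle %||% perox_fixtures()
  net <- assemble_interactome(fx$novel_ppi, fx$known_ppi)
  annotate_building_blocks(net, fx$building_blocks,
                           required = fx$wt_partners$partner)
}
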