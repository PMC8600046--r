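#' Variant interaction profiles (edgotypes)
#'
#' Converts a variant-by-partner interaction matrix into one profile per
#' variant: the partners whose interaction is maintained (1), lost (0) or
#' unstated (NA). The three sets partition the wild-type partner universe.
#'
#' @param matrix_df Wide tibble with a `variant_id` column and one 1/0/NA
#'   column per partner (the fixture `variant_matrix` layout).
#' @return Tibble `variant_id`, `maintained`, `lost`, `unknown` (list
#'   columns of partner symbols), `n_maintained`, `n_lost`, `n_unknown`.
#' @examples
#' fx <- perox_fixtures()
#' variant_profiles(fx$variant_matrix)
#' @export
variant_profiles <- function(matrix_df) {
  stop_missing_cols(matrix_df, "variant_id", "`matrix_df`")
  long <- matrix_df |>
    tidyr::pivot_longer(-"variant_id", names_to = "partner", values_to = "call")
  long |>
    group_by(.data$variant_id) |>
    summarise(
      maintained = list(.data$partner[!is.na(.data$call) & .data$call == 1]),
      lost = list(.data$partner[!is.na(.data$call) & .data$call == 0]),
      unknown = list(.data$partner[is.na(.data$call)]),
      .groups = "drop") |>
    mutate(n_maintained = lengths(.data$maintained),
           n_lost = lengths(.data$lost),
           n_unknown = lengths(.data$unknown)) |>
    arrange(match(.data$variant_id, matrix_df$variant_id))
}

#' Apply a variant's edge losses to the wild-type network
#'
#' Removes the bait-partner edges a variant has lost, leaving every other
#' edge untouched. Partners with unstated (NA) calls are treated as
#' maintained by default and only removed in strict mode.
#'
#' @param wt_net Wild-type `interactome`.
#' @param profile One row of [variant_profiles()] (or a list with
#'   `lost` / `unknown` character vectors).
#' @param bait Bait protein whose edges are perturbed (default "PEX26").
#' @param strict If `TRUE`, unknown partners are removed as well.
#' @return The variant-specific `interactome`.
#' @export
apply_variant_losses <- function(wt_net, profile, bait = "PEX26",
                                 strict = FALSE) {
  bait <- norm_symbol(bait)
  lost <- unlist(profile$lost)
  unknown <- unlist(profile$unknown)
  if (isTRUE(strict)) lost <- c(lost, unknown)
  if (length(lost) == 0) {
    return(wt_net)
  }
  lost <- norm_symbol(lost)
  nbrs <- igraph::neighbors(wt_net, bait)$name
  bad <- setdiff(lost, nbrs)
  if (length(bad)) {
    abort(paste0("lost partner(s) not wild-type neighbors of ", bait, ": ",
                 paste(bad, collapse = ", ")),
          class = "peroxnet_bad_profile")
  }
  eids <- igraph::get_edge_ids(wt_net, rbind(bait, lost))
  out <- igraph::delete_edges(wt_net, eids[eids > 0])
  class(out) <- c("interactome", class(out))
  out
}

#' Assemble the variant edge-loss matrix
#'
#' Builds the binary interaction matrix (rows: WT plus variants; columns:
#' the 18 wild-type partners) from variant profiles, verifying the
#' structural invariants: all profiles cover the same partner universe and
#' the WT row is all ones.
#'
#' @param profiles Tibble from [variant_profiles()].
#' @return An `edge_loss_matrix`: wide tibble (`variant_id` + one column
#'   per partner, cells 1/0/NA) with the partner universe as attribute.
#' @export
build_loss_matrix <- function(profiles) {
  universes <- purrr::pmap(profiles, function(variant_id, maintained, lost,
                                              unknown, ...) {
    sort(c(maintained, lost, unknown))
  })
  if (length(unique(universes)) != 1) {
    abort("profiles cover inconsistent partner universes",
          class = "peroxnet_bad_profile")
  }
  partners <- universes[[1]]
  rows <- purrr::pmap(profiles, function(variant_id, maintained, lost,
                                         unknown, ...) {
    v <- setNames(rep(NA_integer_, length(partners)), partners)
    v[maintained] <- 1L
    v[lost] <- 0L
    c(list(variant_id = variant_id), as.list(v))
  })
  out <- bind_rows(rows)
  if ("WT" %in% out$variant_id) {
    wt <- out |> filter(.data$variant_id == "WT") |> select(-"variant_id")
    if (!all(wt == 1, na.rm = FALSE)) {
      abort("WT row must be all 1", class = "peroxnet_bad_profile")
    }
  }
  structure(out, partners = partners,
            class = c("edge_loss_matrix", class(out)))
}

# Hamming distance (count of disagreeing calls) over pairwise-complete
# columns; NA cells never contribute to any distance.
hamming_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) next
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  as.dist(d)
}

#' Hierarchical clustering of variant edge-loss fingerprints
#'
#' Clusters the rows of the edge-loss matrix with agglomerative
#' hierarchical clustering. The distance is the Hamming distance on the
#' binary profiles, computed over pairwise-complete (non-NA) columns;
#' linkage is complete by default. The flat partition at `k` clusters is
#' reported, plus the sub-partition (again at up to 3 groups) of the
#' largest multi-member cluster -- the screen's "subgroup" structure.
#' Ties in merge order follow the input row order.
#'
#' @param matrix An `edge_loss_matrix` (or compatible wide tibble).
#' @param k Number of main clusters to cut (default 3).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param k_sub Number of subgroups cut inside the largest cluster.
#' @return A `variant_clustering`: list with `hclust` (the dendrogram),
#'   `clusters` (tibble `variant_id`, `cluster`, `subgroup`), `distance`,
#'   `linkage`, `k`.
#' @examples
#' fx <- perox_fixtures()
#' cl <- cluster_variants(build_loss_matrix(variant_profiles(fx$variant_matrix)))
#' cl$clusters
#' @export
cluster_variants <- function(matrix, k = 3L, linkage = "complete",
                             k_sub = 3L) {
  m <- as.matrix(matrix[, setdiff(names(matrix), "variant_id")])
  rownames(m) <- matrix$variant_id
  if (nrow(m) < 2) {
    abort("need at least two rows to cluster", class = "peroxnet_bad_input")
  }
  if (k > nrow(m)) {
    abort("k cannot exceed the number of rows", class = "peroxnet_bad_input")
  }
  d <- hamming_dist(m)
  if (all(d == 0) && k > 1) {
    warn("all profiles identical: dendrogram heights are degenerate")
  }
  hc <- hclust(d, method = linkage)
  main <- cutree(hc, k = k)

  # subgroups: re-cut the largest multi-member cluster's own subtree
  subgroup <- rep(NA_integer_, nrow(m))
  sizes <- table(main)
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- names(main)[main == big]
  if (length(members) >= 3) {
    msub <- m[members, , drop = FALSE]
    hsub <- hclust(hamming_dist(msub), method = linkage)
    subgroup[match(members, rownames(m))] <-
      cutree(hsub, k = min(k_sub, length(members)))
  }
  structure(
    list(hclust = hc,
         clusters = tibble(variant_id = rownames(m),
                           cluster = unname(main),
                           subgroup = subgroup),
         distance = "hamming (pairwise-complete)",
         linkage = linkage, k = k),
    class = "variant_clustering")
}

#' @export
print.variant_clustering <- function(x, ...) {
  cat("<variant_clustering>", x$linkage, "linkage on", x$distance,
      "| k =", x$k, "\n")
  print(x$clusters)
  invisible(x)
}

#' @rdname cluster_variants
#' @param x A `variant_clustering`.
#' @param ... Unused.
#' @export
tidy.variant_clustering <- function(x, ...) x$clusters

#' @rdname cluster_variants
#' @export
glance.variant_clustering <- function(x, ...) {
  tibble(k = x$k, n = length(x$hclust$order),
         distance = x$distance, linkage = x$linkage,
         max_height = max(x$hclust$height))
}

#' Export a variant dendrogram in Newick format
#'
#' @param clustering A `variant_clustering`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  hc <- clustering$hclust
  labs <- hc$labels
  rec <- function(i) {
    if (i < 0) {
      return(labs[-i])
    }
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    paste0("(", rec(kids[1]), ":", h, ",", rec(kids[2]), ":", h, ")")
  }
  writeLines(paste0(rec(nrow(hc$merge)), ";"), path)
  invisible(path)
}

#' Share of a variant's remaining edges per functional building block
#'
#' Normalises each variant's maintained interactions to 100% and reports
#' the percentage falling in each building block.
#'
#' @param profile One row of [variant_profiles()].
#' @param blocks Data frame (`partner`, `block`) covering all partners.
#' @return Tibble `block`, `n_maintained`, `pct` (percentages sum to 100).
#' @export
building_block_impact <- function(profile, blocks) {
  stop_missing_cols(blocks, c("partner", "block"), "`blocks`")
  maintained <- unlist(profile$maintained)
  if (length(maintained) == 0) {
    abort("variant maintains zero edges: per-block shares are undefined",
          class = "peroxnet_zero_edges")
  }
  uncovered <- setdiff(norm_symbol(maintained), norm_symbol(blocks$partner))
  if (length(uncovered)) {
    abort(paste0("blocks mapping missing partner(s): ",
                 paste(uncovered, collapse = ", ")),
          class = "peroxnet_missing_block")
  }
  tibble(partner = norm_symbol(maintained)) |>
    left_join(mutate(blocks, partner = norm_symbol(.data$partner)),
              by = "partner") |>
    count(.data$block, name = "n_maintained") |>
    mutate(pct = 100 * .data$n_maintained / sum(.data$n_maintained))
}

#' Edgetic-perturbation versus disease-phenotype heatmap table
#'
#' For each variant and clinical phenotype, counts how many of the
#' variant's lost partners are associated with that phenotype.
#'
#' @param matrix An `edge_loss_matrix` (or the fixture variant matrix).
#' @param associations Data frame (`gene`, `phenotype`).
#' @return Tibble `variant_id`, `phenotype`, `n_perturbed` (complete grid
#'   over all variants and association phenotypes; empty associations give
#'   a zero-row table).
#' @export
perturbation_phenotype_heatmap <- function(matrix, associations) {
  stop_missing_cols(associations, c("gene", "phenotype"), "`associations`")
  long <- matrix |>
    tidyr::pivot_longer(-"variant_id", names_to = "partner", values_to = "call")
  lost <- long |> filter(!is.na(.data$call) & .data$call == 0)
  if (nrow(associations) == 0) {
    return(tibble(variant_id = character(), phenotype = character(),
                  n_perturbed = integer()))
  }
  grid <- tidyr::expand_grid(variant_id = unique(matrix$variant_id),
                             phenotype = unique(associations$phenotype))
  hits <- lost |>
    inner_join(associations, by = c(partner = "gene"),
               relationship = "many-to-many") |>
    count(.data$variant_id, .data$phenotype, name = "n_perturbed")
  grid |>
    left_join(hits, by = c("variant_id", "phenotype")) |>
    mutate(n_perturbed = tidyr::replace_na(.data$n_perturbed, 0L))
}
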