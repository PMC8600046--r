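profiles <- variant_profiles(fx$variant_matrix)
wt_net <- fixture_interactome(fx)

test_that("profiles partition the 18-partner universe", {
  expect_identical(profiles$n_maintained + profiles$n_lost + profiles$n_unknown,
                   rep(18L, 8))
  for (i in seq_len(nrow(profiles))) {
    expect_length(intersect(profiles$maintained[[i]], profiles$lost[[i]]), 0)
  }
})

test_that("variant-specific networks lose the documented number of edges", {
  deg <- function(net) {
    nd <- interactome_nodes(net)
    nd$degree[nd$protein == "PEX26"]
  }
  l153 <- apply_variant_losses(
    wt_net, dplyr::filter(profiles, variant_id == "p.Leu153Val"))
  expect_identical(deg(l153), 18 - 4)

  p117 <- apply_variant_losses(
    wt_net, dplyr::filter(profiles, variant_id == "p.Pro117Leu"))
  expect_identical(deg(p117), 18 - 10)

  # empty loss set leaves the graph unchanged; only bait edges are touched
  wt <- apply_variant_losses(wt_net, dplyr::filter(profiles, variant_id == "WT"))
  expect_identical(igraph::ecount(wt), igraph::ecount(wt_net))
  non_bait_before <- sum(!grepl("PEX26", attr(igraph::E(wt_net), "vnames")))
  non_bait_after <- sum(!grepl("PEX26", attr(igraph::E(p117), "vnames")))
  expect_identical(non_bait_before, non_bait_after)

  bad <- dplyr::mutate(dplyr::filter(profiles, variant_id == "WT"),
                       lost = list("NOT_A_PARTNER"))
  expect_error(apply_variant_losses(wt_net, bad), class = "peroxnet_bad_profile")
})

test_that("the loss matrix keeps the conserved columns", {
  m <- build_loss_matrix(profiles)
  expect_true(all(m[, c("PEX5", "PEX14", "PEX19", "ECH1", "FIS1", "PXMP2")] == 1))
  variants <- m[m$variant_id != "WT", ]
  expect_true(all(variants[, c("PEX16", "ABCD3", "ACBD5")] == 0))

  wt_only <- build_loss_matrix(dplyr::filter(profiles, variant_id == "WT"))
  expect_identical(dim(wt_only), c(1L, 19L))
  expect_true(all(wt_only[, -1] == 1))

  incompatible <- dplyr::bind_rows(
    dplyr::filter(profiles, variant_id == "WT"),
    dplyr::mutate(dplyr::filter(profiles, variant_id == "WT"),
                  variant_id = "odd", maintained = list(c("X", "Y"))))
  expect_error(build_loss_matrix(incompatible), class = "peroxnet_bad_profile")
})

test_that("hierarchical clustering recovers the three variant classes", {
  m <- build_loss_matrix(profiles)
  cl <- cluster_variants(m, k = 3)
  groups <- split(cl$clusters$variant_id, cl$clusters$cluster)
  grouped <- unname(lapply(groups, sort))
  expect_true(list(sort(c("WT", "p.Leu153Val"))) %in% grouped)
  expect_true(list(sort(c("p.Leu44Pro", "p.Leu45Pro", "p.Gly89Arg",
                          "p.Arg98Trp", "p.Pro118Arg"))) %in% grouped)
  expect_true(list("p.Pro117Leu") %in% grouped)

  # subgroup structure inside the five-variant cluster
  sub <- cl$clusters[!is.na(cl$clusters$subgroup), ]
  sub_groups <- unname(lapply(split(sub$variant_id, sub$subgroup), sort))
  expect_true(list(sort(c("p.Leu44Pro", "p.Leu45Pro"))) %in% sub_groups)
  expect_true(list(sort(c("p.Gly89Arg", "p.Arg98Trp"))) %in% sub_groups)
  expect_true(list("p.Pro118Arg") %in% sub_groups)
})

test_that("clustering is invariant to row permutation up to labels", {
  m <- build_loss_matrix(profiles)
  set.seed(1)
  perm <- m[sample(nrow(m)), ]
  cl1 <- cluster_variants(m, k = 3)$clusters
  cl2 <- cluster_variants(perm, k = 3)$clusters
  part <- function(cl) unname(lapply(split(cl$variant_id, cl$cluster), sort))
  expect_setequal(part(cl1), part(cl2))
})

test_that("degenerate and boundary clusterings behave", {
  m2 <- build_loss_matrix(dplyr::filter(
    profiles, variant_id %in% c("p.Leu44Pro", "p.Leu45Pro")))
  expect_warning(cl <- cluster_variants(m2, k = 2), regexp = "identical")
  expect_identical(cl$hclust$height[1], 0)

  m <- build_loss_matrix(profiles)
  all_k <- cluster_variants(m, k = nrow(m))
  expect_identical(dplyr::n_distinct(all_k$clusters$cluster), nrow(m))
  expect_error(cluster_variants(m, k = 9), class = "peroxnet_bad_input")
})

test_that("NA cells are excluded pairwise from the distance", {
  m <- tibble::tibble(variant_id = c("r1", "r2", "r3"),
                      A = c(1L, 0L, 1L), B = c(1L, NA, 0L), C = c(0L, 0L, 1L))
  d <- as.matrix(peroxnet:::hamming_dist(
    `rownames<-`(as.matrix(m[, -1]), m$variant_id)))
  expect_equal(d["r1", "r2"], 1)  # B dropped pairwise
  expect_equal(d["r2", "r3"], 2)  # A and C differ, B dropped
  expect_equal(d["r1", "r3"], 2)  # B and C differ
})

test_that("dendrogram exports to Newick", {
  cl <- cluster_variants(build_loss_matrix(profiles))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, profiles$variant_id)
})

test_that("building-block shares are percentages of remaining edges", {
  wt <- building_block_impact(dplyr::filter(profiles, variant_id == "WT"),
                              fx$building_blocks)
  expect_equal(sum(wt$pct), 100, tolerance = 1e-9)
  expect_equal(wt$pct[wt$block == "matrix protein import"], 100 * 5 / 18)
  expect_equal(wt$pct[wt$block == "fatty acid metabolism"], 100 * 6 / 18)

  p117 <- building_block_impact(
    dplyr::filter(profiles, variant_id == "p.Pro117Leu"), fx$building_blocks)
  expect_equal(p117$pct[p117$block == "matrix protein import"], 25)
  expect_equal(p117$pct[p117$block == "membrane assembly"], 12.5)
  expect_equal(p117$pct[p117$block == "division and proliferation"], 12.5)
  expect_equal(p117$pct[p117$block == "fatty acid metabolism"], 25)
  expect_equal(p117$pct[p117$block == "unknown"], 25)

  solo <- dplyr::mutate(dplyr::filter(profiles, variant_id == "WT"),
                        maintained = list("PEX5"))
  one <- building_block_impact(solo, fx$building_blocks)
  expect_equal(one$pct, 100)

  none <- dplyr::mutate(dplyr::filter(profiles, variant_id == "WT"),
                        maintained = list(character(0)))
  expect_error(building_block_impact(none, fx$building_blocks),
               class = "peroxnet_zero_edges")
})

test_that("the perturbation heatmap counts lost disease-gene links", {
  heat <- perturbation_phenotype_heatmap(fx$variant_matrix, fx$phenotype_gene)
  wt_row <- dplyr::filter(heat, variant_id == "WT")
  expect_true(all(wt_row$n_perturbed == 0))

  totals <- heat |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(total = sum(n_perturbed))
  expect_identical(
    totals$variant_id[which.max(totals$total)], "p.Pro117Leu")

  empty <- perturbation_phenotype_heatmap(
    fx$variant_matrix, data.frame(gene = character(), phenotype = character()))
  expect_identical(nrow(empty), 0L)

  # row totals are monotone in the number of disease-associated lost partners
  assoc_genes <- unique(fx$phenotype_gene$gene)
  lost_assoc <- variant_matrix_long(fx) |>
    dplyr::filter(!is.na(call), call == 0, partner %in% assoc_genes) |>
    dplyr::count(variant_id)
  merged <- dplyr::inner_join(totals, lost_assoc, by = "variant_id")
  ord <- order(merged$n)
  expect_true(all(diff(merged$total[ord]) >= 0))
})
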