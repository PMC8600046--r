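# shared helpers: tiny graphs and screen scaffolding built in code

fx <- perox_fixtures()

edges_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(protein_a = m[, 1], protein_b = m[, 2])
}

path_net <- function() assemble_interactome(edges_df("A", "B", "B", "C"), NULL)

triangle_net <- function() {
  assemble_interactome(edges_df("A", "B", "B", "C", "C", "A"), NULL)
}

two_triangles_net <- function() {
  assemble_interactome(
    edges_df("A", "B", "B", "C", "C", "A", "X", "Y", "Y", "Z", "Z", "X"), NULL)
}

star_net <- function(k = 4) {
  leaves <- paste0("L", seq_len(k))
  assemble_interactome(data.frame(protein_a = "HUB", protein_b = leaves), NULL)
}

# minimal plate table for hand-specified per-combo ratios of one pair;
# cf is 0 (control wells with zero 535 signal)
plates_from_ratios <- function(ratios, pair = c("AAA", "BBB"),
                               experiment_id = "E1", i_d = 1000) {
  combos <- tidyr::expand_grid(donor_is_a = c(TRUE, FALSE),
                               dt = c("N", "C"), at = c("N", "C"))[seq_along(ratios), ]
  samples <- tibble::tibble(
    experiment_id = experiment_id, plate_id = "P001",
    well_id = sprintf("A%02d", seq_along(ratios)),
    donor_construct = paste0(ifelse(combos$donor_is_a, pair[1], pair[2]), "-", combos$dt),
    acceptor_construct = paste0(ifelse(combos$donor_is_a, pair[2], pair[1]), "-", combos$at),
    donor_terminus = combos$dt, acceptor_terminus = combos$at,
    replicate = 1L,
    intensity_535 = i_d * ratios, intensity_475 = i_d,
    well_class = "sample")
  ctrl <- tibble::tibble(
    experiment_id = experiment_id, plate_id = "P001", well_id = "H01",
    donor_construct = unique(samples$donor_construct),
    acceptor_construct = "YFP-free",
    donor_terminus = NA_character_, acceptor_terminus = NA_character_,
    replicate = 1L, intensity_535 = 0, intensity_475 = i_d,
    well_class = "donor_control")
  dplyr::bind_rows(samples, ctrl)
}

# brute-force normalized betweenness by all-pairs shortest-path enumeration
brute_betweenness <- function(net) {
  g <- igraph::delete_edges(net, igraph::E(net)[igraph::which_loop(net)])
  vs <- igraph::V(g)$name
  n <- length(vs)
  memb <- igraph::components(g)$membership
  csize <- igraph::components(g)$csize
  btw <- setNames(numeric(n), vs)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t <= s || memb[s] != memb[t]) next
      paths <- igraph::all_shortest_paths(g, from = vs[s], to = vs[t])$res
      sigma <- length(paths)
      if (sigma == 0) next
      inner <- unlist(lapply(paths, function(p) setdiff(names(p), vs[c(s, t)])))
      if (length(inner)) {
        tab <- table(inner)
        btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / sigma
      }
    }
  }
  denom <- (csize[memb] - 1) * (csize[memb] - 2) / 2
  out <- ifelse(denom > 0, btw / denom, 0)
  setNames(out, vs)
}
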