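# peroxnet

Edgetic-perturbation analysis of the peroxisomal protein-interaction
network, centred on the membrane peroxin PEX26.

Pathogenic missense variants in *PEX26* cause peroxisome biogenesis
disorders spanning the whole Zellweger spectrum, yet the severity of the
clinical phenotype correlates poorly with the one interaction classically
tested (PEX26-PEX6). The idea behind this package is that a missense
variant does not delete the protein (node removal) but snips specific
interaction edges while the node persists — an *edgetic perturbation* —
and that the pattern of lost edges ("edgotype") is what tracks the
molecular phenotype. `peroxnet` implements the complete analysis chain
for a resonance-energy-transfer interaction screen built around that
idea:

1. **BRET calling.** A protein pair is tested in living cells in all
   eight donor/acceptor fusion combinations, in duplicate wells. The
   BRET ratio of a well is

   *R* = *I*<sub>A</sub> / *I*<sub>D</sub> − *cf*,

   where *I*<sub>A</sub> is the 535 nm (acceptor) intensity,
   *I*<sub>D</sub> the 475 nm (donor, luciferase) intensity, and *cf*
   the correction factor — the mean *I*<sub>A</sub>/*I*<sub>D</sub> of
   control wells in which the donor construct is co-expressed with free
   acceptor. Duplicates are averaged per combination, and a pair is
   called interacting when at least one combination's mean ratio exceeds
   the method-specific threshold (0.094) strictly.
2. **Interactome assembly.** Novel screen edges are merged with a
   curated set of known peroxisomal interactions into one undirected
   graph with edge provenance and functional "building-block" node
   annotation.
3. **Topology.** Degree, normalized betweenness centrality
   (NetworkAnalyzer convention: 2*B*/((n−1)(n−2)) per component),
   average clustering coefficient, density, heterogeneity, Freeman
   degree centralization, Markov-clustering (MCL) modules, and
   node-removal robustness.
4. **Edgetics.** Variant-specific networks, the variant × partner
   edge-loss matrix, hierarchical clustering of binary edge-loss
   fingerprints (Hamming distance, complete linkage), per-building-block
   impact shares, and a variant × disease-phenotype perturbation count
   table.
5. **Phenotype scoring.** A literature-based biochemical score
   (stability 30/15/0 plus three import components at up to 10 points
   each, 60 total for wild type), its Pearson correlation with the
   number of maintained interactions, and a comparative-CT
   (2^−ΔΔCT) expression utility.
6. **Disease network.** Gene-phenotype associations and shared-gene
   disease-disease links overlaid on the interactome as a typed
   heterogeneous graph, with main-component statistics and MCL modules.

A synthetic plate-reading generator (`simulate_screen_plates()`)
produces raw dual-channel well tables with known ground truth — including
per-donor control wells and the bJun-bFos / YFP-Rluc plate controls — so
the whole chain is testable without instrument data. Packaged fixtures
reconstruct the screen's inputs (the 90-protein peroxisomal library, the
18 PEX26 partners, the 67 curated interactions, the 65 gene-phenotype
relationships, per-variant biochemical profiles); files with a
`synthetic_` prefix are reconstructions built to reproduce the published
aggregate values, not original measurements (see `vignette` and
`?perox_fixtures`).

## Worked example

```r
library(peroxnet)
library(dplyr)

fx <- perox_fixtures()

# 1. simulate a noisy screen of PEX26 against the 90-protein library
plates <- simulate_library_screen("PEX26", fx$library90$protein,
                                  fx$wt_partners$partner,
                                  noise_model(ratio_noise_sd = 0.02), seed = 42)
calls <- run_screen(plates, "PEX26", fx$library90$protein)
sum(calls$positive)
#> [1] 18

# 2. merge with curated interactions and inspect the PEX26 component
net <- fixture_interactome(fx)
net
#> <interactome> 48 proteins, 81 interactions
#>   provenance: curated=67, novel=14
topology_report(induced_component(net, "PEX26"))
#> <topology_report> 37 nodes, 74 edges, 1 component(s)
#>   avg clustering 0.273 | density 0.111 | heterogeneity 0.915
#> # A tibble: 5 x 3
#>   protein degree betweenness
#>   <chr>    <dbl>       <dbl>
#> 1 PEX26       18      0.482
#> 2 PEX5        14      0.362
#> 3 PEX19       12      0.201
#> 4 PEX7         7      0.133
#> 5 PEX14        6      0.0578

# 3. cluster the variant edge-loss fingerprints
prof <- variant_profiles(fx$variant_matrix)
cluster_variants(build_loss_matrix(prof))
#> <variant_clustering> complete linkage on hamming (pairwise-complete) | k = 3
#>   variant_id  cluster subgroup
#> 1 WT                1       NA
#> 2 p.Leu44Pro        2        1
#> ...
#> 6 p.Pro117Leu       3       NA
#> 8 p.Leu153Val       1       NA

# 4. correlate maintained interactions with the biochemical score
sc <- biochemical_score(fx$biochem_profiles)
correlate_ppi_score(inner_join(prof, sc, by = "variant_id"))
#> <ppi_score_cor> Pearson r = 0.958 (p = 0.000184, n = 8)
#>   linear fit: score = -31.52 + 5.16 * n_PPI

# 5. integrated protein-disease network
integrated_stats(build_integrated_network(net, fx$phenotype_gene))
#> <integrated_stats> 104 nodes / 158 edges; main component 51 / 119 + 20 further components
#>   main avg clustering 0.376 | 6 MCL modules
```

The wild-type screen establishes 18 binary edges for PEX26 (14 novel +
4 known); PEX26 is the top betweenness hub of its induced 37-node /
74-edge sub-network; the seven missense variants fall into three
clusters (wild-type-like, intermediate with three subgroups, severe);
and the biochemical score tracks the number of maintained interactions
almost linearly.

Plot helpers: `plot_screen_calls()`, `plot_loss_matrix()`,
`plot_perturbation_heatmap()`, `plot_block_impact()`, and `autoplot()`
methods for the correlation and clustering objects. Result objects
support broom-style `tidy()` / `glance()`.

A command-line front end over the same functions ships at
`inst/cli/peroxnet.R` (subcommands `simulate`, `call`, `build`,
`topology`, `remove-node`, `edgetics`, `score`, `disease-net`).

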