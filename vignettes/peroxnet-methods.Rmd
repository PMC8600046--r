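---
title: "Models and methods behind peroxnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peroxnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxnet)
library(dplyr)
```

`peroxnet` analyses a bioluminescence resonance energy transfer (BRET)
interaction screen of the peroxisomal proteome around the membrane
anchor PEX26, and the downstream network-medicine questions: which
interactions a pathogenic missense variant loses, how those losses
distribute over functional modules, and how they relate to biochemical
and clinical phenotypes. This vignette explains the models, the tunable
parameters, the synthetic data generator, the reconstruction status of
the packaged fixtures, and the numerical choices — in more detail than
the function reference.

## The calling model

BRET reports proximity: a luciferase-fused donor excites a
fluorophore-fused acceptor only within molecular distances, so the
ratio of acceptor to donor emission rises above background when the two
proteins interact. Each well gives the ratio

$$R = I_A / I_D - cf,$$

with $I_A$ the 535 nm intensity, $I_D$ the 475 nm intensity and $cf$
the donor construct's background ratio, estimated per experiment as the
mean $I_A/I_D$ over wells of that donor with free acceptor
(`bret_correction_factors()`). Because fusion orientation can occlude
an interaction surface, every pair is tested in all
$2 \times 2 \times 2 = 8$ combinations of donor/acceptor role and
N-/C-terminal fusion, in duplicate. Duplicates are averaged per
combination first; a pair is positive when **any** combination's mean
ratio exceeds the threshold.

Key decisions, all exposed as arguments:

* **Threshold 0.094, strict.** The threshold is method-specific, not
  universal, so `bret_call(threshold =)` exposes it. The comparison is
  strict (`>`): a combination at exactly 0.094 is negative.
* **Average-then-threshold.** Duplicates are biological replicates of
  the same construct pair; the per-combination ratio is their mean, and
  the each-replicate-must-pass alternative is deliberately not used.
* **cf per donor construct per experiment**, because the background is
  a property of the donor fusion protein and drifts between
  experiments.
* **Incomplete combination sets** still produce a call (with
  `n_combos < 8` visible in the output) rather than a hard failure:
  screens lose wells routinely.
* **Confirmation** (`confirm_calls()`) requires a positive primary call
  plus positivity in at least two additional independent experiments.
  Whether a confirmation must reproduce the same combination is not
  fixed by the assay definition; any combination counts here, since
  orientation effects make combination identity across experiments an
  unreliable anchor.

## The synthetic screen generator

`simulate_screen_plates()` emulates the screen's structure, not its
physics: 8 combinations x duplicates per pair, per-donor control wells,
and the two plate controls (the interacting pair bJun-bFos and the
fused YFP-Rluc construct) on every run. The generative model is chosen
to be exactly invertible by the calling formula:

* donor intensity $I_D \sim \mathrm{LogNormal}(\mu, \sigma)$ — plate
  luminescence is positive and right-skewed; defaults
  $\mu = \log 2\times10^4$, $\sigma = 0.4$ arbitrary units;
* acceptor intensity $I_A = I_D (cf + r + \varepsilon)$ with
  $\varepsilon \sim N(0, sd)$, so that $I_A/I_D - cf = r + \varepsilon$
  recovers the underlying ratio exactly;
* true pairs draw $r$ uniformly from `positive_ratio_range`
  (default 0.15–0.6, low end required to clear the threshold) in a
  random non-empty subset of the 8 combinations, reflecting that
  orientation determines which fusions transfer energy; false pairs and
  non-supporting combinations have $r = 0$.

With `ratio_noise_sd = 0` the calls equal the ground truth for any
seed — the zero-noise oracle the test-suite leans on. The generator
does **not** model luminescence decay kinetics, plate-position effects,
transfection-efficiency variation, or intensity-dependent noise; a
passing pipeline therefore demonstrates correctness of the analysis
chain, not robustness to every instrument artefact of real plates.

## Fixtures and their reconstruction status

The screen's input tables are not published as machine-readable data.
The package therefore ships two kinds of fixtures under
`inst/extdata/`:

* **Directly documented tables** (no prefix): the 18 wild-type
  partners with provenance, the 9 splice-variant partners, the
  partner-to-building-block mapping, the truncated-fragment binding
  annotation, and the variant x partner matrix.
* **Synthetic reconstructions** (`synthetic_` prefix): the 90-protein
  library membership beyond the named proteins, the 67 curated
  interactions, the 65 gene-phenotype relationships over 40 phenotypes,
  the per-variant biochemical profiles, and the qPCR cycle thresholds.
  These were rebuilt so that every aggregate the screen reports is
  reproduced: PEX26 degree 18; induced component 37 nodes / 74 edges
  covering about 40% of proteins and 90% of edges; betweenness ranking
  PEX26 (0.48) > PEX5 (0.36) > PEX19 (0.20) > PEX7 (0.13); integrated
  network 104 nodes / 158 edges with a 51-node / 119-edge main
  component and average clustering 0.376; Pearson r 0.958 between
  maintained edges and biochemical score. They are *consistent
  reconstructions*, not measurements; a handful of association entries
  are research-level rather than textbook catalogue entries, and the
  number of satellite components in the integrated network (20 here)
  is one aggregate that a consistent reconstruction cannot pin down
  exactly.

Two cells of the variant matrix deserve note. The variant text fixes
most calls (six partners positive for every variant, three perturbed in
every variant, the four losses of p.Leu153Val, the eight maintained
partners of p.Pro117Leu, and the cluster-2 discriminators PEX6, PEX11B
and FAR1). The calls of cluster-2 variants against PEX12, PEX13,
PEX11G and PXMP4 are not individually stated; they are resolved to
*maintained* here, because the discriminator list is presented as
exhaustive and because PXMP4's isolation is described as unique to
p.Leu153Val. Cells that genuinely cannot be resolved would be stored
`NA` and excluded pairwise from clustering distances — that code path
is active and tested, it is simply not needed by the shipped matrix.

## Topology conventions

All metrics run on the simple graph: self-interactions are kept in the
container (flagged `self_loop`) but never enter degree, betweenness or
clustering. Conventions follow the Cytoscape NetworkAnalyzer tool so
that values are comparable with screen-era literature:

* normalized betweenness $2B / ((n-1)(n-2))$ with $n$ the node's
  *component* size; component-wise normalization is flagged in the
  report whenever the graph is disconnected, since tools differ here;
* average clustering coefficient counts degree-0/1 nodes as 0;
* heterogeneity is $\mathrm{sd}(k)/\bar k$; centralization is Freeman
  degree centralization.

The test suite checks betweenness against a brute-force all-pairs
shortest-path enumeration on random graphs of up to 12 nodes.

## Markov clustering

No R implementation of MCL is available to this package, so
`mcl_modules()` implements it directly on a sparse column-stochastic
matrix: add self-loops, then iterate expansion (power `2`), inflation
(elementwise power, default `2.0`, re-normalised), and pruning
(`1e-5`) until idempotence; attractor rows define the modules. The
granularity of the result is set by the inflation exponent, for which
the screening literature rarely records a value. At the default 2.0
the reconstructed integrated main component resolves into 6 modules
(largest centred on PEX26 and containing the division/proliferation
proteins and the Zellweger-spectrum phenotype nodes); at inflation
1.7 the same component gives 5. The default is kept at the canonical
2.0 rather than tuned to a target module count; tests assert the
partition property and the composition of the PEX26 module, not a
count.

## Variant clustering

The edgotype of a variant is a binary vector over the 18 wild-type
partners. Distances are **Hamming counts** (number of disagreeing
calls) over pairwise-complete columns — Euclidean distance on 0/1 data
is the square root of the same quantity and yields the same tree under
any monotone linkage. Linkage is **complete**; the cluster count is an
explicit parameter (`k = 3`), not derived from a gap criterion,
because the three-class structure is an input of the downstream
analysis rather than a discovery. "Subgroups" are the k = 3 cut of the
largest cluster's own subtree. Ties in merge order follow the input
row order (the WT-first, protein-position order of the fixture);
permutation invariance of the flat partition is tested. On the fixture
this yields {WT, p.Leu153Val}, {p.Leu44Pro, p.Leu45Pro | p.Pro118Arg |
p.Gly89Arg, p.Arg98Trp}, {p.Pro117Leu}.

## Biochemical score and correlation

The score compresses four literature-derived phenotype measurements
into one number: protein stability 30 (wild-type-like), 15 (reduced)
or 0 (absent), plus three import components (catalase, PTS1, PTS2)
mapped linearly from percent import to 0–10 points. The published
weight string lists five numbers ("30-10-10-10-10") for four
components while anchoring the wild-type total at 60; the trailing 10
is read as a typographical repeat and the implementation is
$30 + 10 + 10 + 10 = 60$. The linear percent-to-points mapping is the
simplest monotone map through the two stated anchors (0 → 0,
100% → 10). Correlation with the number of maintained interactions
uses Pearson's r with the two-sided t-test (n − 2 df) and a
least-squares line; interaction strength is deliberately not modelled —
calls are binary, so a variant with a weakened but positive interaction
(p.Leu153Val with PEX6) counts as maintained.

## Integrated disease network

Gene-phenotype associations connect protein nodes to disease nodes;
two diseases are linked when they share at least one gene (unweighted,
shared-gene count kept as an attribute); allelic-series phenotypes
(ZS, NALD, IRD) are distinct nodes. Statistics run on the untyped
projection, because the single published clustering coefficient is a
scalar over the mixed graph. The main component of the reconstruction
has 51 nodes and 119 edges; removal of the gene-phenotype layer
provably disconnects every disease node from every protein node, which
the suite asserts as a layer-invariant.

## Node removal versus edgetic perturbation

`remove_node_analysis()` contrasts the two lesion models. Removing
PEX26 from its induced sub-network leaves the remainder connected —
its partners stay reachable through the PEX19 membrane-targeting hub —
whereas removing PEX26 with PEX19 excluded from the functional network
(the chaperone is not part of mature-peroxisome function) fragments
the graph into multiple components. The report returns before/after
topology, newly isolated nodes, and the component-count change.

## Problem sizes and determinism

The shipped analyses are small (90-protein library, 8 x 18 variant
matrix, 104-node integrated network) and every stochastic element
(well noise, simulated screens, random test graphs) is driven by an
explicit integer seed; the plate generator is byte-identical for a
fixed seed. The noise-robustness property (false-positive rate
monotone in the ratio noise) is checked over 200 simulated screens per
noise level on a 10-protein library, which keeps the whole suite in
the minutes range on one core.

## Known limitations

* The `synthetic_` fixtures are reconstructions; analyses of *real*
  plate exports will differ wherever the original tables differ from
  the reconstruction, and the satellite-component count of the
  integrated network is known not to be reproduced exactly.
* The generator's noise model is additive on the ratio scale and
  ignores plate-position and expression-level effects.
* Confirmation logic treats experiments as exchangeable; batch effects
  between experiments are not modelled.
* MCL module counts depend on the inflation parameter; comparisons
  across studies should fix it explicitly.
* Binding-domain information for truncated fragments is a static
  annotation table; the package does not infer domains.
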