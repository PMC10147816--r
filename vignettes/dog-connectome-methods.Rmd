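---
title: "Methods: from ROI time series to a dog brain connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ROI time series to a dog brain connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the model
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and the numerical conventions adopted where the methodology
leaves choices open.

## 1. The estimand: unique region-to-region coupling

Ordinary correlation between two ROI signals mixes direct coupling with
everything routed through third regions. The pipeline instead estimates
the *semi-partial* (part) correlation: for ROIs $i, j$, the signal of $i$
is residualized on all other ROIs except $j$, and that residual is
correlated with the raw signal of $j$,

$$s(i \to j) = \mathrm{cor}\!\left(x_j,\; x_i - \hat x_i^{(-i,-j)}\right).$$

This isolates the variance in $j$ explained *only* by $i$. The value is
inherently directed; since a single undirected graph is the analysis
target, the two directions are averaged,
$r_{ij} = \tfrac12\big(s(i\to j) + s(j\to i)\big)$ — the least-assumptive
symmetrization. `semipartial_matrix()` computes all pairs at once through
the precision matrix $K = S^{-1}$ of the sample covariance $S$:

$$s(i \to j) = \frac{-K_{ij}}{\sqrt{K_{jj}\,(K_{ii}K_{jj} - K_{ij}^2)\,S_{jj}}},$$

which is algebraically identical to per-pair residualization (the
conditional covariance of a pair given the rest is the inverse of the
corresponding $2\times2$ precision block) but needs one inversion instead
of $p(p-1)$ regressions. The test suite holds the two routes to within
$10^{-8}$ on randomized instances. With only two ROIs the controlling set
is empty and the plain Pearson correlation is returned. The estimator
requires more timepoints than ROIs ($T > p - 1$); rank-deficient inputs
raise an error naming the collinear columns.

A consequence worth knowing: a latent factor shared by *many* regions is
almost entirely explained away by the controlling set, so diffuse global
signals contribute next to nothing to semi-partial edges. Module structure
visible to this estimator must live in variance that pairs of regions
share uniquely. The synthetic generator (section 4) is designed around
this fact.

## 2. Group inference and the two-level threshold

Per-subject matrices are Fisher z-transformed ($z = \mathrm{atanh}\, r$,
variance-stabilizing; correlations at $|r| \ge 1$, possible only in
degenerate synthetic data, are clamped to $\pm(1 - 10^{-7})$ with a
warning). Group inference asks, per edge, whether mean coupling differs
from zero: a one-sample two-sided t-test of $z$ across subjects. Edges
with zero variance and nonzero mean receive an underflow p-value sentinel
plus a warning rather than an exception — again a synthetic-data-only
degeneracy.

Edge-wise tests alone do not control the family-wise error over
$\binom{97}{2} = 4656$ edges. The pipeline mirrors the two-level scheme of
seed-based connectivity software: a per-seed *omnibus* test asks whether a
seed's whole connectivity profile is null. With 33 subjects and 96
connections per seed a parametric multivariate test is rank-deficient, so
the omnibus is a subject-level sign-flip permutation test: the statistic
is the mean over the seed's edges of $|\bar z|$; under the null of
symmetric subject effects, flipping the sign of whole subjects is
exchangeable. With `n_perm = 5000` draws the p-value uses the add-one
correction $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$,
then Benjamini–Hochberg FDR correction across the 97 seeds
(`stats::p.adjust`). An edge survives iff its uncorrected $p < 0.01$
(`edge_alpha`) *and* at least one endpoint has $q < 0.05$ (`seed_alpha`).
On pure-noise cohorts the retained fraction stays far below
$2\times$ `edge_alpha` (tested over 20 replicates); on planted cohorts the
surviving density lands near 11%, inside the 5–30% band typical of fMRI
connectivity graphs.

Retained edges carry weight $|t|$. Correlation-scale weights would be ≪ 1
and make weighted-degree magnitudes uninformative; test-statistic
magnitudes match the scale on which hub tables in this literature are
reported. The alternative $|\bar z|$ weighting is available
(`threshold_edges(..., weight = "abs_mean_z")`). Edges of both signs are
retained — the magnitude enters the graph, the sign is kept in the edge
table.

## 3. Graph topology conventions

The graph keeps all 97 ROIs as nodes; ROIs with no surviving edge are
isolated nodes that count toward density ($2E/(N(N-1))$) but not toward
path lengths. Clustering $C$ (mean binary local clustering, degree-<2
nodes contributing 0), triangle count, and characteristic path length $L$
(mean binary shortest path within connected components — no infinite
distances, no harmonic mean) are computed on the binarized graph:
small-world scalars are classically defined on binary graphs and the
published raw values they are compared against ($C \approx 0.18$,
$L \approx 2.15$) are on that scale.

Null models for $\Gamma = C/C_{rand}$ and $\Lambda = L/L_{rand}$ are
degree-preserving double-edge-swap randomizations
(`igraph::rewire(keeping_degseq)`), 10 attempted swaps per edge, rejecting
self-loops and multi-edges, so the degree multiset is preserved exactly
(property-tested over 50 seeded graphs). `n_null = 100` nulls by default;
$\Sigma = \Gamma/\Lambda$ holds to $10^{-12}$ by construction. A warning
is issued when the largest component covers <90% of nodes, since $L$ then
describes the connected core only.

## 4. The synthetic cohort: what is planted and why

No public canine cohort accompanies this analysis, so the generator
emulates *denoised* ROI time series with exactly the structure the
pipeline claims to detect. Each ROI signal is a linear latent-factor
process with AR(1) temporal correlation:

$$x = \lambda F_{sub} + \lambda_{sup} G + c\,H_{pair}
      + \textstyle\sum_k h\,F_{(k)} + \sigma\,\varepsilon,$$

with every latent component an AR(1) series of unit stationary variance
(coefficient $\phi = 0.4$, a realistic autocorrelation for denoised BOLD
at ~2.6 s sampling) and columns standardized afterwards. The default atlas
has 97 ROIs — 45 bilateral pairs and 7 midline regions — in ten modules:
eight bilateral ones and one twin pair of lateralized 15-ROI
super-modules, each hiding two sub-modules.

* `loading` ($\lambda = 0.8$): within-(sub)module factor loading; the main
  source of module cohesion.
* `homolog_coupling` ($c = 0.35$): pair-specific factor shared by the two
  bilateral homologs. Because it is unique to a pair, the semi-partial
  estimator retains it fully, making homolog edges among the strongest in
  the graph — which reproduces the observed strong left/right symmetry of
  node weight and degree (Spearman rank correlations across pairs ~0.6–0.9
  on default cohorts, with the weight correlation exceeding the degree
  correlation at strong coupling). Values much above ~0.5 glue the two
  lateralized twins into one cross-hemisphere module at layer 1, which is
  why the default sits at 0.35.
* `super_link_prob` / `sub_link_prob` / `super_link_loading`
  (0.3 / 0.6 / 0.4): *pairwise* lateral couplings inside the
  super-modules, drawn once per cohort. A diffuse factor loaded by all 15
  members is invisible to semi-partial correlation (section 1) — measured
  cross-sub-module t-statistics stay ~0.5 even at loading 0.8 — so
  super-module cohesion is planted the way it plausibly arises
  anatomically: sparse region-to-region couplings, denser within a
  sub-module than across. The diffuse super factor
  ($\lambda_{sup} = 0.5$) is kept for marginal-correlation realism.
* `hub_ids`, `hub_loading`, `hub_k` (five pairs, 0.4, 3): hubs load onto
  the three most populous *other* modules. Attaching hub bridges to large
  modules matters: a bridge into a small module can flip Louvain into
  merging the two, whereas large modules' degree-based null term resists
  it.
* `noise_sd` ($\sigma = 1$): with the loadings above this puts planted
  within-module marginal correlations near 0.4 and thresholded-graph
  density near 11–12%.

Defaults were frozen after calibrating to qualitative targets only —
post-threshold density ~12%, a 10-module first layer whose two lateralized
super-modules split into a 12-module second layer, and recoverable hubs —
not to any published effect sizes, which are not available. The generator
does **not** emulate scanner artefacts, motion, scrubbing, susceptibility
dropout, global signal, inter-subject anatomical variability, or
voxel-level structure; subjects are exchangeable draws from one
population. Passing tests therefore demonstrate that the *pipeline*
recovers known structure under realistic noise and autocorrelation — not
that it would behave identically on real, artefact-laden data.

## 5. Communities: consensus and the second layer

Community detection is greedy multi-level (Louvain) maximization of
weighted modularity with a resolution multiplier on the null term,
$Q = \sum_c \left( e_c/m - r\, (d_c/2m)^2 \right)$, at $r = 0.6$ — the
resolution at which the reference analysis found its 10-module structure.
Louvain is stochastic, so the partition is stabilized by consensus voting:
10 repeats with derived seeds, a node×node co-assignment frequency matrix,
frequencies < 0.5 zeroed, re-clustering of the consensus graph, iterated
until the matrix is block-constant (cap 20 iterations, warning on
non-convergence). Consensus is deterministic given (graph, resolution,
repeats, master seed) and at least as accurate as the median of its
repeats on planted benchmarks.

The second layer mirrors the two-round procedure of the reference
analysis: a module is *lateralized* when >70% of its members lie in one
hemisphere (the threshold is a package choice; midline ROIs count toward
neither side), the two most populous lateralized modules are re-clustered
on their induced subgraphs, and labels are renumbered contiguously. On
default cohorts this turns 10 modules into 12 = (10 − 2) + (2 + 2).
Per-community internal densities $2E_c/(n_c(n_c-1))$ are reported
descriptively (singletons flagged with density 0); on default cohorts
every community is denser than the whole graph.

## 6. Centrality and hubs

Weighted degree (strength), binary degree, and betweenness centrality —
Brandes' algorithm on the binarized graph, unnormalized, with fractional
credit for tied shortest paths; non-integer BC values arise naturally from
tie credit and bilateral averaging. Whether published hub tables used
weighted-distance betweenness is usually unstated; binary distances are
the package default and the weighted variant is deliberately out of scope.
Bilateral pairs are averaged *before* ranking (midline ROIs compete
unchanged), ties break alphabetically for byte-reproducible output, and
the consensus hub set intersects the three top-20 lists. On planted
cohorts the consensus set recovers ~95% of hub pairs across replicates;
the occasional miss comes from betweenness, the noisiest of the three
rankings on dense graphs.

## 7. Parcellation comparison

Given a network×ROI overlap-voxel table, each ROI goes to the network with
the largest overlap, with bilateral pair counts averaged before the argmax
so homologs always share an assignment; all-zero ROIs are reported
unallocated, and argmax ties break toward the lowest network row with a
warning (the convention is arbitrary; real overlap counts never tie).
Two parcellations are compared by one-to-one matching on ROI-set Jaccard
similarity, greedy by descending score — matching published tables that
pair networks by inspection — with an exhaustive optimal matcher available
(`method = "optimal"`). Only one-to-one scores are computed; many-to-many
"partial" correspondences are a manual judgement the package does not
formalise. The Jaccard of two empty sets is an error, not 0.

## 8. Reproducibility conventions

A single master seed drives everything: `derive_seeds()` spawns one child
seed per stochastic stage (permutations, null models, consensus repeats,
split), so stages re-run in isolation reproduce the pipeline run exactly;
all generator and RNG state is restored on exit. Reports are
byte-identical across runs of the same cohort, configuration and seed, and
carry the configuration hash and all stage seeds. Problem sizes used
throughout the test suite — cohorts of 33×264×97 for end-to-end checks,
4–8-ROI instances for estimator oracles, 20-replicate noise studies —
were chosen so the full suite exercises the complete default study
conditions.

## 9. Known limitations

* The semi-partial estimator needs $T > p$; atlases finer than the
  timepoint count require shrinkage estimators that are out of scope.
* $L$ averages within components; graphs fragmenting under stricter
  thresholds change meaning silently apart from the <90%-component
  warning.
* The resolution parameter is treated as the single free scalar of the
  modularity quality function; other software may parameterize its
  community routine differently, so numeric resolutions are not portable
  across tools.
* Negative-edge handling (magnitude weights, sign kept as an attribute) is
  one of several defensible conventions; signed-modularity analysis is not
  implemented.
* The generator's homolog coupling is global; region-specific asymmetries
  (e.g. language-like lateralization of coupling strength) are not
  modelled.
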