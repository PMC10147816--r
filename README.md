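# dogconn

Resting-state functional connectome analysis of the dog brain: a complete,
reproducible pipeline from denoised ROI time series to a thresholded
weighted brain graph, its small-world topology, two-layer consensus
community structure, bilateral-averaged hub rankings, and Jaccard
comparison between network-to-ROI parcellations.

The package is aimed at network-neuroscience practitioners who want the
whole chain — first-level connectivity, group inference, graph metrics,
modularity, centrality — as tested, seeded, re-runnable code. Because
canine resting-state datasets are rarely public, the package ships a
synthetic-cohort generator that plants every structure the analysis is
supposed to find (modules, lateralized super-modules, bilateral homolog
coupling, hub nodes), so each stage can be validated against known ground
truth.

## The analysis

**First level.** For ROIs $i, j$ with signals $x_i, x_j$, the directed
semi-partial correlation is

$$s(i \to j) = \mathrm{cor}\big(x_j,\; x_i - \hat{x}_i^{(-i,-j)}\big),$$

where $\hat{x}_i^{(-i,-j)}$ is the OLS prediction of $x_i$ from all ROIs
except $i$ and $j$ — the unique contribution of $i$ to $j$ after
discounting every other region. The symmetrized value
$r_{ij} = (s(i \to j) + s(j \to i))/2$ is Fisher z-transformed,
$z_{ij} = \mathrm{atanh}\, r_{ij}$. Computation uses the precision-matrix
identity $s(i \to j) = -K_{ij} / \sqrt{K_{jj}(K_{ii}K_{jj}-K_{ij}^2)S_{jj}}$
(one matrix inversion per subject), verified in the tests against explicit
per-pair residualization.

**Second level.** Per edge, a one-sample t-test of $z_{ij}$ across subjects
against zero. Per seed ROI, an omnibus sign-flip permutation test of the
mean $|\bar z|$ over its edges, BH-FDR corrected across ROIs. An edge is
retained iff its uncorrected $p < 0.01$ and at least one endpoint has
omnibus $q < 0.05$; retained edges are weighted by $|t|$.

**Graph topology.** On the binarized graph: density $2E/(N(N-1))$,
triangle count, mean local clustering $C$, characteristic path length $L$
(within components), and the small-world scalars
$\Gamma = C/C_{rand}$, $\Lambda = L/L_{rand}$, $\Sigma = \Gamma/\Lambda$
against degree-preserving double-edge-swap null graphs.

**Communities.** Weighted Louvain modularity at resolution 0.6 with
consensus voting over 10 repeats (co-assignment matrix, threshold 0.5,
iterate to block-constancy). A second layer re-clusters the two most
populous lateralized modules (>70% single-hemisphere membership) on their
induced subgraphs. Per-community internal densities and Spearman
correlations between left/right homolog degree and node weight are
reported.

**Hubs.** Weighted degree, degree, and unnormalized Brandes betweenness;
bilateral pairs averaged *before* ranking; consensus hubs are the
intersection of the three top-20 lists.

**Parcellation comparison.** ROIs are allocated to networks by
overlap-voxel majority vote (pairs averaged before the argmax) and two
parcellations are matched one-to-one by greedy descending Jaccard
$|A \cap B| / |A \cup B|$.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort (33 subjects × 264 volumes × 97 ROIs; 45 bilateral pairs,
ten planted modules of which two are lateralized 15-ROI super-modules, five
planted hub pairs):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_connectivity.R
Rscript analysis/03_network.R
Rscript analysis/04_communities.R
Rscript analysis/05_centrality.R
Rscript analysis/06_parcellation.R
```

which prints (seed 1):

```
494 of 4656 edges survive the two-level threshold (10.6%)
graph: N = 97, E = 494, density = 0.1061, triangles = 954
  C = 0.669 (null 0.107)   L = 2.682 (null 2.197)
  gamma = 6.28   lambda = 1.22   sigma = 5.14
layer 1: 10 modules (Q = 0.816); final: 12 modules
community densities all exceed whole-graph density: TRUE
layer-1 ARI against planted modules: 1
homolog symmetry: rho_degree = 0.77 (p = 5.1e-10), rho_weight = 0.56 (p = 5.6e-05)
10 consensus hubs (top-20 in all three metrics): ... roi001, roi002, roi005, roi019, roi020 ...
planted hub pairs recovered: 5/5
mean Jaccard over matched networks: 0.885
```

Reading: the two-level threshold keeps ~11% of possible edges (the density
band reported for fMRI connectivity graphs is 5–30%); the graph is strongly
small-world ($\Sigma \gg 1$); layer-1 consensus clustering recovers the ten
planted modules exactly and the second layer splits both lateralized
super-modules, giving 12 final communities, every one denser than the graph
as a whole; all five planted hub pairs land in the consensus hub set; and
the two jittered parcellations agree at mean Jaccard 0.89. The same
pipeline is available as a single call:

```r
library(dogconn)
co <- simulate_cohort(seed = 1)
report <- run_pipeline(co$meta, co$ts, pipeline_config(seed = 1),
                       overlap_a = co$overlap_a, overlap_b = co$overlap_b)
print(report)
```

## Vignette

`vignettes/dog-connectome-methods.Rmd` documents the statistical model
behind every stage, the generator's design (what it emulates and what it
deliberately does not), the meaning and defaults of each tunable parameter,
and the package's numerical conventions and limitations.
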