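---
title: "Persistent homology phenotyping of 3D root system architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent homology phenotyping of 3D root system architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootph)
```

## The model

A root system is represented as a `voxel_set`: the occupied integer lattice
points of the volume, with a physical voxel spacing. Coordinates are stored in
a canonical lexicographic order, so vertex indices — and everything derived
from them — are reproducible across readers and runs. The depth axis is `z`,
increasing downward; the "top" of the root is its minimal-`z` slice.

`build_network()` connects voxels under 26-connectivity (all lattice
neighbours within Chebyshev distance 1) and assigns each edge its Euclidean
length: `spacing`, `spacing * sqrt(2)` or `spacing * sqrt(3)` for face, edge
and corner neighbours. Two per-vertex descriptor functions are defined on the
resulting `root_network`:

- `geodesic_function()`: the shortest-path distance through the network from
  the top voxel slice, computed exactly with Dijkstra's algorithm
  (`igraph::distances` with multiple sources). It requires a connected
  network; `largest_component()` restricts disconnected inputs first.
- `depth_function()`: `(z - min(z)) * spacing`.

### Superlevel-set persistence

For a function `f` on the network, the filtration is the family of subgraphs
induced by `{v : f(v) >= t}` as `t` decreases, where an edge enters at the
minimum of its endpoint values. `h0_barcode()` tracks connected components:
a component is *born* at the value of its maximal vertex (typically a root
tip) and *dies* when it merges into a component with an older (larger) birth,
at the merge edge's value. This is the elder rule: at a merge, the bar with
the smaller birth dies. The single component that never dies is the
*essential* bar; its death is recorded as 0 and it is flagged in an
`essential` column, since non-essential merges can also legitimately occur at
value 0. Zero-persistence pairs (birth equal to death) carry no information
and are dropped.

Births and deaths are taken directly from vertex and edge values, not from a
discretized level sweep, so barcodes are exact and independent of any step
size. The union–find implementation breaks merge ties (equal births)
deterministically.

On a tree-structured root with the geodesic function, every bar corresponds
to exactly one root tip, so the number of bars equals the tip count. The test
suite verifies this law on 100 generated roots, and verifies against an
independent igraph oracle that at every integer threshold the number of alive
bars equals the number of components of the superlevel subgraph.

### Comparing barcodes

`bottleneck_distance()` computes the exact bottleneck distance between
persistence diagrams: the smallest `eps` such that a perfect matching exists
between the two diagrams (augmented with diagonal projections) with all
matched pairs within L∞ distance `eps`. The implementation binary-searches
the finite set of candidate costs and tests feasibility with an
augmenting-path bipartite matching; it is validated against an exhaustive
matching oracle and satisfies the metric axioms and the stability bound
`d_B(D(f), D(g)) <= max |f - g|` in the test suite. `combined_distance()` is
the Euclidean combination `sqrt(geodesic^2 + depth^2)` of the two per-function
distances.

### From distances to traits

`compute_ph_traits()` produces the trait table:

- **G_PCs**: classical MDS (`stats::cmdscale`, keeping coordinates for
  positive eigenvalues only) of the geodesic bottleneck distance matrix,
  followed by PCA of the scores, keeping the smallest number of components
  reaching 80% of variance.
- **GH_PCs**: the same applied to the combined distance matrix (80%).
- **PDD_PCs**: each geodesic diagram is vectorized by an isotropic bivariate
  Gaussian kernel density estimate with bandwidth 20, evaluated on a fixed
  grid over `[-20, 2000]^2` with node spacing 20 (102 nodes per axis, 10404
  values, birth axis varying fastest), then PCA keeps components to 95%.

Because classical MDS scores are already principal coordinates, PCA on them
returns the scores up to sign; the PCA step is retained to fix an explicit,
deterministic orientation (the largest-magnitude loading of every component is
made positive) and to apply the variance-retention rule uniformly. Bottleneck
distance matrices are in general non-Euclidean, so negative MDS eigenvalues
are expected and their coordinates are discarded; variance fractions are
reported over the positive spectrum. A population of identical roots has an
all-zero distance matrix and raises a degenerate-embedding error rather than
fabricating coordinates.

The KDE grid reads the published "resolution 20" as the node spacing of the
evaluation grid, which together with bandwidth 20 and the stated bounds fixes
the vector length. Each diagram's density is normalized by its number of
points, so the vector integrates to approximately unit mass regardless of how
many bars a root has.

### Trait selection and genetics

`vif_values()` computes the variance inflation factor `1 / (1 - R²)` of each
trait regressed on all others; `vif_prune()` removes the worst trait
(greedy maximum, ties broken toward the later column) until all pass a
threshold, logging every removal. The threshold itself follows the log-curve
rule: sweep the threshold, count retained traits, fit
`y = a * ln(x - b) + c` by nonlinear least squares (`minpack.lm::nlsLM`), and
take the point where the fitted slope equals 1, which is `x = a + b`. For the
published fit `a = 15.71`, `b = 0.8853` this gives the "high" threshold
16.5953; the "median" threshold is its half, 8.29765, with the conventional
rounded value 8 attached as an attribute rather than silently substituted.
When a sweep is flat (no collinearity to resolve), the fit is degenerate and
the pipeline falls back to the fixed default threshold with a warning.

`heritability()` uses method-of-moments one-way variance components:
`Vr` is the within-genotype mean square, `Vg = (MSB - MSW) / ñ` with `ñ` the
standard unbalanced-design effective replicate number, floored at zero, and
`H² = Vg / (Vg + Vr/nrep)` with `nrep` the mean replicate count. The estimator
is cross-checked against `lme4::lmer` on balanced data in the tests.
`allele_effect_size()` scales an estimate by the major-allele mean, and
`colocalize_tas()` merges trait-associated SNPs transitively within a 1 Mb
window per chromosome and reports per-group Venn counts.

## The synthetic generator

`generate_root()` rasterizes one primary axis growing in `+z` with optional
lateral jitter (tortuosity), plus a Poisson-distributed number of laterals
with controlled lengths, insertion depths and soil angles. Laterals are drawn
with a digital differential analyzer normalized so the dominant axis advances
one voxel per step, which makes each branch a monotone, self-avoiding voxel
path. To keep the whole root a tree (cycle rank 0) under 26-connectivity, the
primary takes a one-voxel lateral "jog" at each insertion site and the
lateral's first voxel leaves opposite that jog one plane deeper; candidate
laterals whose voxels touch anything other than the insertion voxel are
rejected and redrawn, and the whole root is retried if needed. Every accepted
root carries exact ground truth: tip count, per-branch length, insertion
depth and angle.

The generator is a study stand-in, not a biophysical model: it produces
tree-structured, downward-growing herringbone architectures on a unit grid.
It does not model root thickness (volumes are one voxel wide),
second-order laterals, curvature of laterals after emission beyond the DDA
line, or gravitropic bending. `perturb_voxels()` adds boundary noise while
preserving connectivity, which is how the tests probe robustness to
non-tree inputs.

Population sizes used in the pipeline defaults and tests (tens of plants,
two replicates) are this package's own choices, sized so the full suite runs
in about a minute; all statistical machinery is independent of these sizes.

## Design decisions and limitations

- Bars are reported with `birth >= death` (superlevel convention) and exactly
  one essential bar per connected network, death capped at 0.
- `select_num_pcs()` uses `>=` against the variance threshold with a small
  numerical tolerance, so a component set summing exactly to the threshold is
  accepted.
- PDD vectors are computed from geodesic diagrams by default; the function is
  selectable (`kde_fun = "depth"`).
- VIF requires more samples than traits. On small simulated populations the
  pipeline pre-reduces the panel by dropping the highest-numbered PCs, with a
  message, before pruning.
- All randomness flows from a single seed through derived per-sample seeds,
  and the run manifest excludes timestamps, so pipeline bundles are
  byte-identical across reruns.
- The bottleneck implementation is exact but quadratic in candidate costs; it
  is intended for population-scale diagram sizes (tens to hundreds of bars),
  not for massive diagrams.
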