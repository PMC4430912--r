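---
title: "Anatomy packing with hierarchical segments: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy packing with hierarchical segments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphs)
```

## The problem

A pulmonary-nodule region of interest (ROI) from a CT slice contains several
anatomical structures with overlapping intensity ranges: dark lung
parenchyma, the bright chest/lung wall, vessels and ground-glass opacity at
intermediate brightness, and the solid nodule core. The goal is a complete
semantic labeling of the ROI -- every pixel assigned to exactly one of K
anatomical classes -- driven by a handful of user scribbles ("seeds"), one
small stroke per structure.

The package decomposes this into three stages:

1. a **multi-scale hierarchy** of image partitions (statistical region
   merging run at a ladder of scale parameters),
2. a **segmentation tree** and **ultrametric contour map (UCM)**
   summarizing that hierarchy, and
3. **anatomy packing**: selecting a set of tree segments, one label each,
   that covers the ROI exactly and minimizes a conditional random field
   (CRF) energy.

## Stage 1: statistical region merging and the nested ladder

`run_srm()` implements statistical region merging: all 4-adjacent pixel
pairs are visited in ascending order of absolute intensity difference, and
two regions are merged when the difference of their mean intensities is
within a statistical bound,
\[
|\bar R - \bar R'| \le \sqrt{b^2(R) + b^2(R')},\qquad
b^2(R) = \frac{g^2 \ln(1/\delta)}{2 Q\,|R|},
\]
with `g = 256` gray levels and `delta = 1/(6 |I|^2)`. The scale parameter
`Q` controls granularity: larger `Q` tightens the bound and yields more
regions. This concentration-only bound is the package default because it
makes the scale behavior clean and predictable (a noiseless two-intensity
image splits into exactly its two regions at `Q = 1`, and region counts are
monotone in `Q` in practice). The fuller merging bound with an extra
region-complexity term `min(g, |R|) ln(1 + |R|)` is available as
`srm_params(bound = "nock")`; it is substantially looser on small regions
(it happily merges 128-pixel regions of means 0 and 255 at `Q = 1`), which
is statistically defensible but makes small-`Q` partitions degenerate on
small ROIs -- hence it is opt-in rather than default.

`build_nested_ladder()` runs SRM at the finest scale (largest `Q`) on
pixels, then repeatedly coarsens the *region* adjacency graph at each
smaller `Q`, so the levels are nested by construction; a final root level
(the whole ROI) is appended. `build_tree()` collapses regions that persist
across levels into single nodes, producing the segmentation tree: leaves
are the finest regions, the root is the ROI, and node ids increase from
leaves to root. `compute_ucm()` assigns each interpixel boundary the level
at which its two sides first merge; thresholding the UCM at level
`lambda` (`threshold_ucm()`) reproduces the ladder level exactly, which is
tested as an invariant.

## Stage 2: the label model

Seeds (`seeds_from_raster()`) feed `build_histograms()`: one intensity
histogram per class over `bins = 64` bins, Laplace-smoothed with
`epsilon = 1e-6` so log-likelihoods stay finite. The unary cost of giving
segment `S` label `k` is the summed negative log-likelihood
\(\sum_{p \in S} -\log h_k(b(I_p))\), which is additive over the tree
(cost of a parent = sum over its children), so all node unaries come from
one pass over the leaves (`node_unaries()`).

The pairwise term is a contrast-modulated Potts penalty on 4-adjacent
pixels with different labels, \(\gamma \exp(-\beta\,\Delta I^2)\), with
`gamma = 50` by default and `beta = "auto"` set to
\(1 / (2\,\overline{\Delta I^2})\) -- the standard choice that puts the
kernel's soft threshold at the image's own contrast scale. Only pairs
crossing finest-region boundaries can ever be cut, so the weights are
aggregated per adjacent leaf pair once (`leaf_edge_weights()`).

## Stage 3: anatomy packing as tree-constrained inference

A valid labeling selects tree segments such that every root-to-leaf path
contains **exactly one** selected segment (completeness + non-overlap;
`validate_labeling()`). For two labels the global optimum is found exactly
by a single min-cut: each node carries two binary variables ("at or below
a segment selected with label A / label B"), monotone down the tree and
mutually exclusive, with unary costs charged on the edge where a selection
becomes maximal. All terms are submodular, so `solve_binary_pylon()`
reduces the problem to one `igraph::max_flow()` call. Exactness is tested
against exhaustive enumeration of all valid labelings on random trees.

For K > 2, `solve_multilabel()` runs alpha-expansion: each move is a binary
problem (keep the current label vs switch to alpha) solved by the same
exact cut, accepted only if the energy strictly decreases; the expansion
tables satisfy the triangle (submodularity) condition because the Potts
weights are nonnegative. The energy trace is therefore strictly
decreasing, another tested invariant. When hard seed pins are in use
(`hard_seeds = TRUE` puts infinite unary cost on non-seeded labels of
seeded leaves), a whole-ROI initial labeling can be infeasible and
single-label moves can deadlock; the solver then initializes with every
leaf at its cheapest admissible label, which restores convergence.

## Evaluation metrics

`evaluate_boundaries()` compares a computer boundary against n manual
delineations:

* **Average distance** (`average_distance()`): symmetric mean of minimal
  point-to-set distances between two boundary point sets.
* **Modified Williams index** (`williams_index()`): ratio of mean
  computer-to-observer agreement (`1/AD`) to mean inter-observer
  agreement. The default `"standard"` denominator averages over unordered
  observer pairs, so a value near 1 means "the computer agrees with the
  panel as well as the panel agrees internally". An alternative
  `"printed"` form -- the ordered double sum with prefactor
  `2/(n(n-2))` as the index is sometimes typeset -- is available; it
  rescales the index by `(n-2)/(2(n-1))` (e.g. about 1/3 at `n = 4`), so
  its values are not comparable to 1.
* **Percentage statistic** (`percentage_statistic()`): fraction of
  (nodule, reference observer) pairs where the computer is within the
  maximum inter-observer distance.
* **Overlapping/difference ratios** (`overlap_difference()`): Jaccard
  overlap with the majority-vote manual region and its complement, so
  `OR + DR = 1` by construction.

## The phantom and simulated observers

Clinical CT data cannot ship with the package, so `make_nodule_phantom()`
builds a 128 x 128 (by default) four-class scene that emulates the
*topology and intensity ordering* of a part-solid nodule ROI after
windowing to `[0, 255]`: parenchyma (mean 30), a wall band along the left
edge (210), a ground-glass halo (110) with an embedded solid core (230),
and a thin bright vessel (180) crossing the parenchyma -- five distinct
shades over four semantic classes, since vessel and GGO share a class but
not an intensity. Gaussian noise of chosen standard deviation is added
with a fixed seed; seed strokes are generated strictly inside each
structure. What the phantom does **not** emulate: CT reconstruction
texture (noise is i.i.d., not streaky or correlated), partial-volume
blur at boundaries (edges are step edges), irregular nodule margins
(spiculation, lobulation), and anatomy outside the four classes. Results
on it bound what the pipeline can do on clean geometry; they do not
certify clinical performance.

`simulate_observers()` produces manual-style delineations by displacing
the traced ground-truth contour radially with a smooth low-order Fourier
field of chosen RMS amplitude (about 2 px by default, 3 harmonics) --
enough structure to give a realistic inter-observer spread while keeping
the curves closed and star-shaped.

## Numerical choices and problem sizes

* Union-find with path halving and pooled region statistics makes SRM a
  single sorted pass; a 128 x 128 ROI segments in well under a second and
  a full 9-level ladder plus inference runs in a few seconds.
* Max-flow problems have `2 N + 2` vertices for `N` tree nodes; typical
  trees here have tens of nodes, so the cuts are trivial for
  `igraph::max_flow()`. Infinite costs are clamped to a finite big-M (four
  times the sum of finite costs) before the flow call.
* Histogram bins default to 64 so that 8-bit intensities quantize 4:1,
  which keeps seed histograms dense enough from strokes of a few dozen
  pixels.
* All randomness (phantom noise, observers) is seeded and restores the
  caller's RNG state (`with_seed()`), so runs are reproducible
  bit-for-bit; `aphs_export()` writes a manifest sufficient to re-run a
  configuration.

## Limitations

* Alpha-expansion is exact only for K = 2; for K > 2 it returns a strong
  local optimum (no single expansion move can improve it).
* The labeling granularity is bounded by the finest SRM partition: if the
  finest level merges two true structures, no labeling can separate them.
  Raising `q_max` refines the leaves at the cost of a larger tree.
* Intensity histograms ignore texture; structures distinguishable only by
  texture need different features.
* The Williams index is undefined when observers coincide
  (`evaluate_boundaries()` degrades it to `NA`), and infinite when the
  computer coincides with an observer.
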