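# aphs — anatomy packing with hierarchical segments

Seed-driven multi-label semantic segmentation of pulmonary-nodule regions
of interest (ROIs) in CT slices, in base R.

A nodule ROI contains several structures with overlapping intensity
ranges — dark parenchyma, the bright lung wall, vessels and ground-glass
opacity, the solid nodule core. Given one small scribble per structure,
`aphs()` produces a complete labeling of the ROI (every pixel in exactly
one of K classes) in three stages:

1. **Hierarchy.** Statistical region merging is run over a ladder of scale
   parameters Q; two regions merge when their mean intensities satisfy
   |R̄ − R̄′| ≤ √(b²(R) + b²(R′)) with b²(R) = g² ln(1/δ) / (2Q|R|). The
   ladder is nested by construction and is summarized as a segmentation
   tree and an ultrametric contour map (UCM): each interpixel boundary
   carries the scale at which it vanishes, and thresholding the UCM at
   level λ reproduces the ladder level exactly.
2. **Label model.** Per-class intensity histograms h_k are built from the
   seeds; the cost of giving tree segment S label k is
   Σ_{p∈S} −log h_k(b(I_p)), additive over the tree. Adjacent pixels with
   different labels pay γ·exp(−β ΔI²).
3. **Packing.** Inference selects tree segments, one label each, so that
   every root-to-leaf path holds exactly one selected segment, minimizing
   the CRF energy E = U + V. For K = 2 this is solved **exactly** by a
   single min-cut over a tree-structured binary encoding; for K > 2,
   alpha-expansion repeats that exact binary cut until no move lowers the
   energy.

Four boundary-agreement metrics compare a result against multiple manual
delineations: the average boundary distance, the modified Williams index,
the percentage statistic, and the overlapping/difference ratios. A
synthetic four-class nodule phantom and a simulated-observer generator
make the whole pipeline testable without clinical data.

## Worked example

```r
library(aphs)

ph  <- make_nodule_phantom(nodule_phantom_spec(size = 128, noise_sigma = 8))
fit <- aphs(ph$image, ph$seeds)
fit
#> Anatomy packing with hierarchical segments
#>   ROI: 128 x 128 pixels; K = 4 classes; Q ladder: 1, 2, 4, 8, 16, 32, 64, 128, 256
#>   tree: 8 segments (6 leaves); final energy: 43204.61

summary(fit)
#> APHS segmentation of a 128 x 128 ROI into 4 classes
#>   class pixel fractions: 1: 72.5%, 2: 12.5%, 3: 12.3%, 4: 2.7%
#>   6 of 8 tree segments selected (sizes 8071, 3808, 2047, 1680, 441, 337)
#>   energy: 112831.18 -> 43204.61 over 3 accepted moves (2 sweeps)

mean(fit$labels == ph$truth)
#> [1] 0.999939

obs <- simulate_observers(ph$truth == 4, n_observers = 4, amplitude = 2, seed = 2)
evaluate_run(fit, obs)
#> Boundary agreement vs 4 manual delineations
#>   modified Williams index: 0.825
#>   percentage statistic:    25.00%
#>   overlapping ratio:       0.743
#>   difference ratio:        0.257

plot(fit)                 # color-coded labels
plot(fit, type = "ucm")   # contour saliencies
aphs_export(fit, "run1")  # PNGs, UCM edge list, tree JSON, manifest
```

Real rasters are read with `load_roi()` (8/16-bit PNG or TIFF; 16-bit
inputs are min-max rescaled with the transform recorded in the result).
A thin command-line front end lives at `inst/cli/aphs.R`
(`phantom` / `segment` / `eval` subcommands).

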