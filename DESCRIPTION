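Package: aphs
Title: Anatomy Packing with Hierarchical Segments for Multi-Label ROI Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-driven multi-label semantic segmentation of pulmonary-nodule
    regions of interest in CT slices. Builds a multi-scale statistical region
    merging hierarchy, represents it as a nested segmentation tree and an
    ultrametric contour map, and assigns semantic labels (parenchyma, lung
    wall, vessel/ground-glass opacity, solid nodule) to tree segments by
    minimizing a tree-constrained conditional random field energy with
    graph cuts (exact for two labels) or alpha-expansion. Includes the four
    boundary-agreement metrics used to compare computer-generated boundaries
    against multiple manual delineations (modified Williams index, percentage
    statistic, overlapping and difference ratios) and a synthetic phantom
    generator with simulated observers so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
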