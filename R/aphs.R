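#' Anatomy packing with hierarchical segments
#'
#' Full seeded multi-label segmentation of a grayscale ROI:
#' (1) a ladder of nested statistical-region-merging partitions over the Q
#' ladder, (2) the segmentation tree and ultrametric contour map of the
#' hierarchy, (3) per-class intensity histograms from the seed scribbles,
#' (4) tree-constrained CRF inference -- an exact graph cut for two
#' classes, alpha-expansion for more.
#'
#' @param img Intensity matrix on `[0, 255]` (see [load_roi()]).
#' @param seeds Seed raster (integer matrix, 0 = unlabeled) or an
#'   `"aphs_seeds"` object; the number of classes K is taken from it.
#' @param q_max Largest Q of the ladder; the ladder is all powers of two
#'   from 1 to `q_max`.
#' @param q_values Explicit ascending Q ladder (overrides `q_max`).
#' @param gamma Pairwise weight.
#' @param beta Contrast scale, or `"auto"`.
#' @param bins,epsilon Histogram model parameters.
#' @param hard_seeds If `TRUE`, leaf segments containing seed pixels are
#'   pinned to the seeded class (infinite unary cost on other labels);
#'   by default seeds act only through the histograms.
#' @param max_sweeps Alpha-expansion sweep cap.
#' @param bound SRM merging bound (see [srm_params()]).
#' @param g Gray-level count.
#' @return Object of class `"aphs"`: `labels` (pixel label matrix),
#'   `labeling` (per-segment label vector), `tree`, `ucm`, `ladder`,
#'   `model`, `energy` (final), `trace` (energy after each accepted move),
#'   `params`, `K`.
#' @examples
#' ph <- make_nodule_phantom(nodule_phantom_spec(size = 64,
#'                                               noise_sigma = 0))
#' fit <- aphs(ph$image, ph$seeds, q_max = 16)
#' mean(fit$labels == ph$truth)
#' @export
aphs <- function(img, seeds, q_max = 256, q_values = NULL, gamma = 50,
                 beta = "auto", bins = 64, epsilon = 1e-6,
                 hard_seeds = FALSE, max_sweeps = 10,
                 bound = "concentration", g = 256) {
  img <- as_gray_image(img, g = g)
  if (is.matrix(seeds)) seeds <- seeds_from_raster(seeds)
  if (!identical(seeds$dim, dim(img))) stop("seed raster shape mismatch")
  K <- seeds$K
  if (is.null(q_values)) q_values <- 2^(0:floor(log2(q_max)))
  ladder <- build_nested_ladder(img, q_values, bound = bound, g = g)
  tree <- build_tree(ladder)
  ucm <- compute_ucm(ladder)
  model <- build_histograms(img, seeds, bins = bins, epsilon = epsilon, g = g)
  U <- node_unaries(tree, img, model)
  if (hard_seeds) U <- pin_seeded_leaves(U, tree, seeds)
  beta_val <- resolve_beta(beta, img)
  edges <- leaf_edge_weights(img, ladder$levels[[1L]], gamma, beta_val)
  params <- energy_params(gamma = gamma, beta = beta_val, K = K)
  if (K == 2) {
    y <- solve_binary_pylon(tree, U, edges)
    trace <- labeling_energy(tree, y, U, edges)
    sweeps <- 1L
  } else {
    sol <- solve_multilabel(tree, U, edges, K = K, max_sweeps = max_sweeps)
    y <- sol$y
    trace <- sol$energy
    sweeps <- sol$sweeps
  }
  structure(list(labels = labeling_to_pixelmap(tree, y), labeling = y,
                 tree = tree, ucm = ucm, ladder = ladder, model = model,
                 unaries = U, edges = edges,
                 energy = trace[length(trace)], trace = trace,
                 sweeps = sweeps, params = params, K = K,
                 q_values = q_values, hard_seeds = hard_seeds,
                 img = img, call = match.call()),
            class = "aphs")
}

# pin leaves containing seed pixels to the seeded class; leaves seeded
# with several classes keep the majority class (with a warning)
pin_seeded_leaves <- function(U, tree, seeds) {
  reg <- tree$finest$region
  for (k in seq_len(seeds$K)) {
    for (leaf in unique(reg[seeds$pixels[[k]]])) {
      counts <- vapply(seq_len(seeds$K), function(kk)
        sum(reg[seeds$pixels[[kk]]] == leaf), integer(1))
      maj <- which.max(counts)
      if (sum(counts > 0) > 1L && maj != k) {
        warning("leaf segment seeded with several classes; pinned to the majority class")
      }
      U[leaf, -maj] <- Inf
    }
  }
  U
}

#' @export
print.aphs <- function(x, ...) {
  cat("Anatomy packing with hierarchical segments\n")
  cat(sprintf("  ROI: %d x %d pixels; K = %d classes; Q ladder: %s\n",
              nrow(x$labels), ncol(x$labels), x$K,
              paste(x$q_values, collapse = ", ")))
  cat(sprintf("  tree: %d segments (%d leaves); final energy: %.2f\n",
              x$tree$n_nodes, length(x$tree$leaves), x$energy))
  invisible(x)
}

#' @export
summary.aphs <- function(object, ...) {
  areas <- tabulate(object$labels, nbins = object$K)
  sel <- which(object$labeling > 0)
  out <- list(
    dim = dim(object$labels), K = object$K,
    class_areas = areas,
    class_fraction = areas / length(object$labels),
    n_segments = object$tree$n_nodes,
    n_selected = length(sel),
    selected_sizes = object$tree$size[sel],
    energy_trace = object$trace,
    sweeps = object$sweeps,
    gamma = object$params$gamma, beta = object$params$beta
  )
  class(out) <- "summary.aphs"
  out
}

#' @export
print.summary.aphs <- function(x, ...) {
  cat(sprintf("APHS segmentation of a %d x %d ROI into %d classes\n",
              x$dim[1], x$dim[2], x$K))
  cat("  class pixel fractions:",
      paste(sprintf("%d: %.1f%%", seq_len(x$K), 100 * x$class_fraction),
            collapse = ", "), "\n")
  cat(sprintf("  %d of %d tree segments selected (sizes %s)\n",
              x$n_selected, x$n_segments,
              paste(sort(x$selected_sizes, decreasing = TRUE),
                    collapse = ", ")))
  cat(sprintf("  energy: %.2f -> %.2f over %d accepted moves (%d sweeps)\n",
              x$energy_trace[1], x$energy_trace[length(x$energy_trace)],
              length(x$energy_trace) - 1L, x$sweeps))
  invisible(x)
}

#' Plot an APHS segmentation
#'
#' @param x An `"aphs"` fit.
#' @param type `"labels"` (color-coded classes), `"ucm"` (contour
#'   saliencies at double resolution) or `"image"` (the input ROI).
#' @param ... Passed to [graphics::image()].
#' @export
plot.aphs <- function(x, type = c("labels", "ucm", "image"), ...) {
  type <- match.arg(type)
  flip <- function(m) t(m)[, nrow(m):1, drop = FALSE]   # raster orientation
  switch(type,
    labels = graphics::image(flip(x$labels), col = c("#2e8b2e", "#3050c8",
                                                     "#e0d020", "#c03030")[seq_len(x$K)],
                             axes = FALSE, asp = 1, ...),
    ucm = graphics::image(flip(ucm_raster(x$ucm)),
                          col = grDevices::gray.colors(64, 1, 0),
                          axes = FALSE, asp = 1, ...),
    image = graphics::image(flip(x$img), col = grDevices::gray.colors(256, 0, 1),
                            axes = FALSE, asp = 1, ...)
  )
  invisible(x)
}

#' Evaluate a segmentation against manual delineations
#'
#' Extracts the boundary of one class of an APHS result (or takes a mask)
#' and computes the four agreement metrics.
#'
#' @param fit An `"aphs"` object or a logical mask.
#' @param observers List of observer boundary curves or masks.
#' @param label Class whose region is compared (default: the largest label,
#'   the solid nodule in the 4-class convention).
#' @param ... Passed to [evaluate_boundaries()].
#' @return An `"aphs_metrics"` report.
#' @export
evaluate_run <- function(fit, observers, label = NULL, ...) {
  mask <- if (inherits(fit, "aphs")) {
    if (is.null(label)) label <- fit$K
    fit$labels == label
  } else fit
  evaluate_boundaries(mask, observers, dim = dim(mask), ...)
}

#' Export all artifacts of a run
#'
#' Writes the label raster (palette and integer PNG), the UCM (PNG render
#' and lossless edge list), the tree JSON, and a manifest with the
#' configuration -- enough to reproduce the run bit for bit.
#'
#' @param fit An `"aphs"` object.
#' @param dir Output directory (created if needed).
#' @export
aphs_export <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_png(fit$labels, file.path(dir, "labels.png"))
  write_label_png(fit$labels, file.path(dir, "labels_raw.png"), palette = FALSE)
  write_gray_png(round(ucm_raster(fit$ucm) * 255), file.path(dir, "ucm.png"))
  write_ucm_edges(fit$ucm, file.path(dir, "ucm_edges.tsv"))
  write_tree_json(fit$tree, file.path(dir, "tree.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("aphs")),
    dim = dim(fit$labels), K = fit$K, q_values = fit$q_values,
    gamma = fit$params$gamma, beta = fit$params$beta,
    bins = fit$model$bins, epsilon = fit$model$epsilon,
    hard_seeds = fit$hard_seeds, energy = fit$energy,
    energy_trace = fit$trace, sweeps = fit$sweeps
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
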