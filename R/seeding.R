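# Seed scribbles -> per-class intensity histogram models.  Seeds are soft
# prior information by default: they only shape the histograms; optionally
# the leaf segments containing seeds can be pinned to the seeded class.

#' Build a seed set from an integer raster
#'
#' @param seed_img Integer matrix, same shape as the ROI; 0 = unlabeled,
#'   `k` = seed stroke of class `k`.
#' @param K Number of classes; defaults to `max(seed_img)`.  Every class
#'   `1..K` must have at least one seed pixel.
#' @return Object of class `"aphs_seeds"`: `K`, `pixels` (list of linear
#'   pixel indices per class), `dim`.
#' @export
seeds_from_raster <- function(seed_img, K = NULL) {
  if (!is.matrix(seed_img)) stop("seed raster must be a matrix")
  vals <- as.integer(seed_img)
  if (is.null(K)) K <- max(vals, 0L)
  if (K < 2) stop("need seeds for at least 2 classes")
  pixels <- lapply(seq_len(K), function(k) which(vals == k))
  empty <- which(!vapply(pixels, length, integer(1)))
  if (length(empty)) {
    stop("no seed pixels for class ", paste(empty, collapse = ", "))
  }
  structure(list(K = K, pixels = pixels, dim = dim(seed_img)),
            class = "aphs_seeds")
}

# bin index (1..B) of each intensity on equal-width bins over [0, g-1]
intensity_bins <- function(x, model) {
  pmin(model$bins, floor(x / model$g * model$bins) + 1L)
}

#' Per-class intensity histogram models from seed pixels
#'
#' Seed-pixel intensities of each class are histogrammed over `bins`
#' equal-width bins on `[0, g-1]`, add-epsilon smoothed and renormalized,
#' so every bin probability is strictly positive.
#'
#' @param img Intensity matrix.
#' @param seeds An `"aphs_seeds"` object (or a seed raster).
#' @param bins Number of bins.
#' @param epsilon Smoothing constant.
#' @param g Gray-level count.
#' @return Object of class `"aphs_histmodel"`: `h` (`bins x K` column-
#'   normalized matrix), `bins`, `g`, `epsilon`.
#' @export
build_histograms <- function(img, seeds, bins = 64, epsilon = 1e-6, g = 256) {
  if (is.matrix(seeds)) seeds <- seeds_from_raster(seeds)
  model <- list(bins = bins, g = g, epsilon = epsilon)
  h <- vapply(seq_len(seeds$K), function(k) {
    b <- intensity_bins(img[seeds$pixels[[k]]], model)
    n <- length(b)
    (tabulate(b, nbins = bins) + epsilon) / (n + bins * epsilon)
  }, numeric(bins))
  model$h <- h
  structure(model, class = "aphs_histmodel")
}

#' @export
print.aphs_histmodel <- function(x, ...) {
  cat(sprintf("Histogram model: %d classes, %d bins on [0, %d], epsilon = %g\n",
              ncol(x$h), x$bins, x$g - 1L, x$epsilon))
  invisible(x)
}
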