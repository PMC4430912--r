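# Grayscale ROI images are plain numeric matrices (rows x cols) with
# intensities on [0, g-1]; g = 256 throughout unless stated otherwise.

#' Validate and coerce a grayscale image
#'
#' @param x Numeric matrix of intensities.
#' @param g Number of gray levels; intensities must lie in `[0, g-1]`.
#' @return The matrix, invisibly validated.
#' @export
as_gray_image <- function(x, g = 256) {
  if (!is.matrix(x) || !is.numeric(x)) stop("image must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("image must have at least one pixel")
  if (anyNA(x)) stop("image contains NA intensities")
  if (min(x) < 0 || max(x) > g - 1) {
    stop(sprintf("intensities must lie in [0, %d]", g - 1L))
  }
  x
}

#' Load a region-of-interest raster
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF and returns an intensity
#' matrix on `[0, 255]`.  16-bit (or out-of-range) inputs are min-max rescaled
#' to `[0, 255]`; the affine transform used is recorded in the `"rescale"`
#' attribute so that the mapping back to the original scale is reproducible.
#'
#' @param path File path; format inferred from the extension.
#' @param rescale If `TRUE` (default) min-max rescale non-8-bit inputs.
#' @return Numeric matrix with attribute `"rescale" = c(offset, slope)` such
#'   that `original = offset + slope * value`.
#' @export
load_roi <- function(path, rescale = TRUE) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported raster format: ", ext)
  )
  if (length(dim(raw)) == 3L) {
    chans <- dim(raw)[3L]
    same <- all(vapply(seq_len(chans), function(k) {
      isTRUE(all.equal(raw[, , k], raw[, , 1L]))
    }, logical(1)))
    if (!same) stop("multi-channel raster is not grayscale")
    raw <- raw[, , 1L]
  }
  # readPNG/readTIFF return values on [0,1]; 8-bit data sits on the 255-step
  # lattice. Detect bit depth from the finest step present.
  v255 <- raw * 255
  if (max(abs(v255 - round(v255))) < 1e-6) {
    img <- round(v255)
    attr(img, "rescale") <- c(offset = 0, slope = 1)
  } else if (rescale) {
    lo <- min(raw); hi <- max(raw)
    if (hi > lo) {
      img <- round((raw - lo) / (hi - lo) * 255)
      attr(img, "rescale") <- c(offset = lo * 65535, slope = (hi - lo) * 65535 / 255)
    } else {
      img <- array(0, dim = dim(raw))
      attr(img, "rescale") <- c(offset = lo * 65535, slope = 1)
    }
  } else {
    img <- round(raw * 65535)
    attr(img, "rescale") <- c(offset = 0, slope = 1)
  }
  as_gray_image(structure(img, dim = dim(raw),
                          rescale = attr(img, "rescale")))
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img Intensity matrix on `[0, 255]`.
#' @param path Output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write an integer label raster as PNG
#'
#' Labels are written both ways the pipeline needs them: as a color-coded
#' RGB PNG (`1` green parenchyma, `2` blue wall, `3` yellow vessel/GGO,
#' `4` red solid nodule; `0` black) when `palette = TRUE`, or as a plain
#' 8-bit integer raster (one gray level per label id, lossless for up to
#' 256 labels) otherwise.
#'
#' @param labels Integer matrix with values in `0..255`.
#' @param path Output path.
#' @param palette Use the 4-class color code.
#' @export
write_label_png <- function(labels, path, palette = TRUE) {
  if (!palette) {
    if (max(labels) > 255 || min(labels) < 0) {
      stop("label ids must lie in 0..255 for the raw raster")
    }
    png::writePNG(labels / 255, path)
    return(invisible(path))
  }
  cols <- rbind(c(0, 0, 0), c(0, .7, 0), c(0, 0, 1), c(1, 1, 0), c(1, 0, 0))
  k <- pmin(as.integer(labels), 4L) + 1L
  rgb <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(cols[k, ch], nrow(labels))
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read an integer label raster written by [write_label_png()]
#' @param path PNG path written with `palette = FALSE`.
#' @return Integer matrix.
#' @export
read_label_png <- function(path) {
  round(png::readPNG(path) * 255)
}

# All 4-adjacent interpixel couples of an H x W image, in the canonical
# order: row-major over pixels, right neighbour before down neighbour.
# Returns linear (column-major) indices p1, p2 plus the canonical key.
adjacent_pairs <- function(H, W) {
  p1 <- integer(0); p2 <- integer(0); key <- integer(0)
  if (W > 1L) {
    r <- rep(seq_len(H), times = W - 1L)
    c <- rep(seq_len(W - 1L), each = H)
    p1 <- c(p1, r + (c - 1L) * H)
    p2 <- c(p2, r + c * H)
    key <- c(key, ((r - 1L) * W + (c - 1L)) * 2L)
  }
  if (H > 1L) {
    r <- rep(seq_len(H - 1L), times = W)
    c <- rep(seq_len(W), each = H - 1L)
    p1 <- c(p1, r + (c - 1L) * H)
    p2 <- c(p2, r + 1L + (c - 1L) * H)
    key <- c(key, ((r - 1L) * W + (c - 1L)) * 2L + 1L)
  }
  o <- order(key, method = "radix")
  list(p1 = p1[o], p2 = p2[o], key = key[o])
}
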