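# Synthetic phantoms: nested-intensity test images for the hierarchy
# modules, a four-class lung-ROI phantom (dark parenchyma, bright wall
# band, solid core, intermediate ground-glass halo, thin bright vessel)
# for the end-to-end pipeline, and simulated observer delineations as
# smoothly perturbed ground-truth contours.  All generators are pure
# functions of their arguments and seed.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Nested-disk phantom
#'
#' Concentric disks of the given intensities on a square image: the first
#' intensity is the background, subsequent ones fill disks of decreasing
#' radius.  The ground-truth partition is returned alongside.
#'
#' @param levels Vector of at least two distinct intensities.
#' @param size Side length in pixels.
#' @return List with `image` (intensity matrix) and `truth` (integer matrix
#'   of ground-truth region ids, `1` = background, outermost disk `2`, ...).
#' @export
make_nested_phantom <- function(levels = c(40, 120, 220), size = 64) {
  if (length(levels) < 2L) stop("need at least two intensity levels")
  if (anyDuplicated(levels)) stop("intensity levels must be distinct")
  m <- length(levels)
  ctr <- (size + 1) / 2
  r <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  radii <- size * seq(0.42, 0.12, length.out = m - 1L)
  truth <- matrix(1L, size, size)
  for (k in seq_len(m - 1L)) truth[r <= radii[k]] <- k + 1L
  image <- matrix(levels[truth], size, size)
  list(image = image, truth = truth)
}

#' Specification of the four-class nodule phantom
#'
#' Geometry and intensities of a part-solid nodule ROI: dark parenchyma,
#' a bright wall band along the left edge, a solid core with a ground-glass
#' halo, and a thin bright vessel crossing the parenchyma.  Intensity
#' defaults emulate lung CT after rescaling to `[0, 255]`.
#'
#' @param size Side length (pixels).
#' @param wall_width Width of the wall band (pixels).
#' @param core_center Row/column of the nodule center (defaults to
#'   `0.56 * size`).
#' @param core_radius,halo_radius Radii of the solid core and its
#'   ground-glass halo.
#' @param vessel_row Center row of the horizontal vessel.
#' @param vessel_halfwidth Vessel half-thickness (total width `2h+1`).
#' @param means Named intensities for `parenchyma`, `wall`, `ggo`,
#'   `vessel`, `solid`.
#' @param noise_sigma Additive Gaussian noise SD (clipped to `[0, 255]`).
#' @param rng_seed Seed for the noise.
#' @return An object of class `"nodule_phantom_spec"`.
#' @export
nodule_phantom_spec <- function(size = 128, wall_width = round(size / 8),
                                core_center = round(c(0.56, 0.56) * size),
                                core_radius = round(0.09 * size),
                                halo_radius = round(0.20 * size),
                                vessel_row = round(0.28 * size),
                                vessel_halfwidth = 1,
                                means = c(parenchyma = 30, wall = 210,
                                          ggo = 110, vessel = 180,
                                          solid = 230),
                                noise_sigma = 0, rng_seed = 1) {
  spec <- list(size = size, wall_width = wall_width,
               core_center = core_center, core_radius = core_radius,
               halo_radius = halo_radius, vessel_row = vessel_row,
               vessel_halfwidth = vessel_halfwidth, means = means,
               noise_sigma = noise_sigma, rng_seed = rng_seed)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (anyDuplicated(means)) stop("structure mean intensities must be distinct")
  if (core_radius >= halo_radius) stop("halo must enclose the core")
  if (core_center[2] - halo_radius <= wall_width + 2 ||
      core_center[2] + halo_radius >= size - 1 ||
      core_center[1] - halo_radius <= 2 ||
      core_center[1] + halo_radius >= size - 1) {
    stop("nodule geometry overflows the ROI or touches the wall")
  }
  if (abs(vessel_row - core_center[1]) <= halo_radius + 2 + vessel_halfwidth) {
    stop("vessel crosses the nodule")
  }
  structure(spec, class = "nodule_phantom_spec")
}

#' Generate the four-class nodule phantom
#'
#' Semantic classes: `1` parenchyma, `2` lung wall, `3` vessel/GGO,
#' `4` solid nodule.  A seed raster with one interior stroke per connected
#' structure is generated alongside; every seed pixel lies strictly inside
#' its class region.
#'
#' @param spec A [nodule_phantom_spec()].
#' @return List with `image`, `truth` (K = 4 label matrix), `seeds`
#'   (integer matrix, 0 = unlabeled) and `spec`.
#' @export
make_nodule_phantom <- function(spec = nodule_phantom_spec()) {
  if (!inherits(spec, "nodule_phantom_spec")) stop("need a nodule_phantom_spec")
  s <- spec$size
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  truth <- matrix(1L, s, s)                       # parenchyma
  shade <- matrix(spec$means[["parenchyma"]], s, s)
  truth[cols <= spec$wall_width] <- 2L            # wall band
  shade[cols <= spec$wall_width] <- spec$means[["wall"]]
  vess <- abs(rows - spec$vessel_row) <= spec$vessel_halfwidth &
    cols > spec$wall_width
  truth[vess] <- 3L                               # vessel (class 3)
  shade[vess] <- spec$means[["vessel"]]
  d <- sqrt((rows - spec$core_center[1])^2 + (cols - spec$core_center[2])^2)
  truth[d <= spec$halo_radius] <- 3L              # GGO halo (class 3)
  shade[d <= spec$halo_radius] <- spec$means[["ggo"]]
  truth[d <= spec$core_radius] <- 4L              # solid core
  shade[d <= spec$core_radius] <- spec$means[["solid"]]
  image <- if (spec$noise_sigma > 0) {
    with_seed(spec$rng_seed, {
      matrix(pmax(0, pmin(255, round(shade + rnorm(s * s, 0, spec$noise_sigma)))),
             s, s)
    })
  } else shade
  seeds <- matrix(0L, s, s)
  stroke <- function(r1, r2, c1, c2, k) {
    seeds[r1:r2, c1:c2] <<- k
  }
  cc <- spec$core_center
  # parenchyma: below the nodule, right of the wall
  stroke(min(s - 3, cc[1] + spec$halo_radius + 6),
         min(s - 2, cc[1] + spec$halo_radius + 8),
         spec$wall_width + 8, min(s - 8, spec$wall_width + 38), 1L)
  # wall: vertical stroke mid-band
  stroke(round(0.2 * s), round(0.8 * s),
         max(2, round(spec$wall_width / 2) - 1),
         max(3, round(spec$wall_width / 2) + 1), 2L)
  # GGO: short stroke inside the halo, outside the core
  stroke(cc[1] - 1, cc[1] + 1,
         cc[2] + spec$core_radius + 2, cc[2] + spec$halo_radius - 3, 3L)
  # vessel: stroke along the vessel midline
  stroke(spec$vessel_row, spec$vessel_row,
         spec$wall_width + 6, spec$wall_width + 26, 3L)
  # solid: small block at the core center
  stroke(cc[1] - 2, cc[1] + 2, cc[2] - 2, cc[2] + 2, 4L)
  stopifnot(all(truth[seeds > 0] == seeds[seeds > 0]))
  list(image = image, truth = truth, seeds = seeds, spec = spec)
}

#' Simulate observer delineations of a region
#'
#' Each observer is the ground-truth contour displaced radially by a smooth
#' zero-mean random field (a low-order Fourier series in the polar angle)
#' of the given amplitude.
#'
#' @param mask Logical matrix: the (simply connected, star-shaped) region.
#' @param n_observers Number of delineations (>= 3 for the Williams index).
#' @param amplitude Root-mean-square radial displacement in pixels.
#' @param harmonics Number of low-frequency harmonics in the field.
#' @param seed RNG seed.
#' @return List of `n_observers` boundary curves, each an `N x 2` matrix of
#'   `(x = col, y = row)` pixel-center coordinates forming a closed contour.
#' @export
simulate_observers <- function(mask, n_observers = 4, amplitude = 2,
                               harmonics = 3, seed = 1) {
  if (n_observers < 3) stop("need at least 3 observers")
  if (amplitude < 0) stop("amplitude must be >= 0")
  bd <- extract_boundary(mask)
  ctr <- c(mean(which(mask, arr.ind = TRUE)[, 2]),
           mean(which(mask, arr.ind = TRUE)[, 1]))   # (x, y)
  dx <- bd[, 1] - ctr[1]; dy <- bd[, 2] - ctr[2]
  theta <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  if (amplitude >= min(r)) stop("amplitude exceeds the region inradius")
  with_seed(seed, lapply(seq_len(n_observers), function(o) {
    delta <- rep(0, length(theta))
    for (h in seq_len(harmonics)) {
      ab <- stats::rnorm(2, 0, amplitude / sqrt(harmonics))
      delta <- delta + ab[1] * cos(h * theta) + ab[2] * sin(h * theta)
    }
    rr <- pmax(0.5, r + delta)
    cbind(x = ctr[1] + rr * cos(theta), y = ctr[2] + rr * sin(theta))
  }))
}
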