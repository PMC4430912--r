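# Boundary-agreement metrics: the average boundary distance, the modified
# Williams index, the percentage statistic, and the overlapping/difference
# ratios comparing one computer-generated boundary against n manual
# delineations of the same nodule.

#' Extract the outer boundary contour of a region mask
#'
#' Moore-neighbour tracing of the 8-connected outer contour; points are
#' pixel centers in `(x = col, y = row)` coordinates, ordered along the
#' contour (closed: the last point is 8-adjacent to the first).
#'
#' @param mask Logical matrix with a single connected foreground region.
#' @return `N x 2` matrix of boundary points.
#' @export
extract_boundary <- function(mask) {
  if (!any(mask)) stop("empty region")
  H <- nrow(mask); W <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c]
  # start: first foreground pixel in raster (row-major) order
  idx <- which(t(mask))[1L]
  sr <- (idx - 1L) %/% W + 1L; sc <- (idx - 1L) %% W + 1L
  # Moore neighbourhood, clockwise starting from W
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  pts <- matrix(c(sc, sr), 1L, 2L)
  if (sum(mask) == 1L) {
    stop("region is a single pixel; no closed contour")
  }
  cur <- c(sr, sc)
  dir <- 1L   # backtrack direction: came from the west
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8L
      nr <- cur[1] + moves[d + 1L, 1]; nc <- cur[2] + moves[d + 1L, 2]
      if (inside(nr, nc)) {
        cur <- c(nr, nc)
        # new backtrack: direction pointing back toward the previous pixel,
        # advanced by one for the clockwise scan
        dir <- (d + 6L) %% 8L
        found <- TRUE
        break
      }
    }
    if (!found) stop("region is a single pixel; no closed contour")
    if (cur[1] == sr && cur[2] == sc) break
    pts <- rbind(pts, c(cur[2], cur[1]))
    if (nrow(pts) > 4L * (H * W)) stop("boundary tracing failed to close")
  }
  if (nrow(pts) < 3L) stop("degenerate region: contour has fewer than 3 points")
  colnames(pts) <- c("x", "y")
  pts
}

#' Average distance between two boundaries
#'
#' Symmetric mean of minimal point-to-set Euclidean distances:
#' `AD = (mean_i min_j ||y_j - x_i|| + mean_j min_i ||x_i - y_j||) / 2`.
#'
#' @param X,Y `N x 2` point matrices (columns x, y).
#' @return Distance in pixels.
#' @export
average_distance <- function(X, Y) {
  if (!is.matrix(X) || nrow(X) < 1L || !is.matrix(Y) || nrow(Y) < 1L) {
    stop("boundaries must be non-empty point matrices")
  }
  d2 <- outer(X[, 1], Y[, 1], "-")^2 + outer(X[, 2], Y[, 2], "-")^2
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Modified Williams index
#'
#' Ratio of the computer-to-observer boundary agreement (mean of `1/AD`)
#' to the inter-observer agreement.  The default `"standard"` denominator
#' is the classical form, the mean of `1/AD` over unordered observer
#' pairs, which makes an index near 1 mean "the computer agrees with the
#' observers as well as they agree with each other".  The `"printed"` form
#' evaluates the ordered double sum with prefactor `2 / (n (n - 2))`
#' exactly as often typeset, which rescales the index by
#' `(n - 2) / (2 (n - 1))`.
#'
#' @param computer Computer boundary (`N x 2` matrix).
#' @param observers List of `n >= 3` observer boundaries.
#' @param denominator_form `"standard"` or `"printed"`.
#' @return The index (dimensionless).
#' @export
williams_index <- function(computer, observers,
                           denominator_form = c("standard", "printed")) {
  denominator_form <- match.arg(denominator_form)
  n <- length(observers)
  if (n < 3L) stop("need at least 3 observers")
  ad_co <- vapply(observers, function(o) average_distance(computer, o),
                  numeric(1))
  pairs <- utils::combn(n, 2)
  ad_oo <- apply(pairs, 2, function(p) {
    average_distance(observers[[p[1]]], observers[[p[2]]])
  })
  if (any(ad_oo == 0)) {
    stop("degenerate observers: identical delineations make the inter-observer agreement undefined")
  }
  if (any(ad_co == 0)) {
    # computer identical to an observer: agreement is infinite
    return(Inf)
  }
  num <- mean(1 / ad_co)
  den <- switch(denominator_form,
    standard = mean(1 / ad_oo),
    printed = 2 / (n * (n - 2)) * 2 * sum(1 / ad_oo)
  )
  num / den
}

#' Percentage statistic
#'
#' Over all (nodule, reference observer) pairs, the percentage of
#' computer-to-observer distances not exceeding the corresponding maximum
#' inter-observer distance (the maximum distance between the reference
#' observer and the remaining `n - 1` delineations).
#'
#' @param ds_list List of delineation sets; each element is a list with
#'   `computer` (boundary matrix) and `observers` (list of boundaries).
#' @return Percentage in `[0, 100]`.
#' @export
percentage_statistic <- function(ds_list) {
  if (!is.null(ds_list$computer)) ds_list <- list(ds_list)
  hits <- 0L; total <- 0L
  for (ds in ds_list) {
    n <- length(ds$observers)
    if (n < 2L) stop("need at least 2 observers per nodule")
    ad <- matrix(0, n, n)
    for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
      ad[j, k] <- ad[k, j] <-
        average_distance(ds$observers[[j]], ds$observers[[k]])
    }
    for (j in seq_len(n)) {
      d_cj <- average_distance(ds$computer, ds$observers[[j]])
      hits <- hits + (d_cj <= max(ad[j, -j]))
      total <- total + 1L
    }
  }
  100 * hits / total
}

#' Overlapping and difference ratios
#'
#' `OR = |A .. B| / |A u B|` and `DR = |A xor B| / |A u B|` for the
#' computer region `A` and the average manual region `B`; by construction
#' `OR + DR = 1`.
#'
#' @param computer_region,manual_region Logical matrices (or pixel index
#'   vectors) of the two regions.
#' @return Named vector `c(OR, DR)`.
#' @export
overlap_difference <- function(computer_region, manual_region) {
  A <- if (is.logical(computer_region)) which(computer_region) else computer_region
  B <- if (is.logical(manual_region)) which(manual_region) else manual_region
  if (!length(A) || !length(B)) stop("regions must be non-empty")
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  c(OR = inter / uni, DR = (uni - inter) / uni)
}

#' Majority-vote average of manual regions
#'
#' The "average manually delineated region": pixels covered by at least
#' half (`>= ceiling(n/2)`) of the observers.
#'
#' @param masks List of logical matrices of identical dimension.
#' @return Logical matrix.
#' @export
mean_manual_region <- function(masks) {
  if (!length(masks)) stop("need at least one observer region")
  votes <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  votes >= ceiling(length(masks) / 2)
}

#' Rasterize a closed boundary curve to a region mask
#'
#' Even-odd (crossing-number) point-in-polygon test on the pixel-center
#' grid.
#'
#' @param curve `N x 2` matrix of `(x, y)` vertices of a closed polygon.
#' @param dim Image dimensions `c(H, W)`.
#' @return Logical matrix.
#' @export
curve_to_mask <- function(curve, dim) {
  H <- dim[1]; W <- dim[2]
  px <- rep(seq_len(W), each = H)   # x = col
  py <- rep(seq_len(H), times = W)  # y = row
  n <- nrow(curve)
  xs <- curve[, 1]; ys <- curve[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, H * W)
  for (e in seq_len(n)) {
    y1 <- ys[e]; y2 <- ye[e]
    if (y1 == y2) next
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (xe[e] - xs[e]) * (py - y1) / (y2 - y1) + xs[e])
    inside <- xor(inside, cross)
  }
  matrix(inside, H, W)
}

#' Full agreement report for one nodule
#'
#' Computes the four metrics for a computer region against a set of
#' observer delineations (curves, or masks from which contours are
#' traced).
#'
#' @param computer Logical mask or boundary curve of the computer result.
#' @param observers List of observer boundary curves or masks.
#' @param dim Image dimensions (required when observers are curves and the
#'   computer is a mask, for rasterization).
#' @param denominator_form Passed to [williams_index()].
#' @return Object of class `"aphs_metrics"`: a list with `williams_index`,
#'   `percentage_statistic`, `overlapping_ratio`, `difference_ratio`, and
#'   the underlying `ad_computer` / `ad_observers` distances.
#' @export
evaluate_boundaries <- function(computer, observers, dim = NULL,
                                denominator_form = "standard") {
  if (is.logical(computer)) {
    comp_mask <- computer
    comp_curve <- extract_boundary(computer)
    if (is.null(dim)) dim <- base::dim(computer)
  } else {
    comp_curve <- computer
    if (is.null(dim)) stop("dim is required to rasterize a computer curve")
    comp_mask <- curve_to_mask(computer, dim)
  }
  obs_curves <- lapply(observers, function(o) {
    if (is.logical(o)) extract_boundary(o) else o
  })
  obs_masks <- lapply(observers, function(o) {
    if (is.logical(o)) o else curve_to_mask(o, dim)
  })
  wi <- tryCatch(
    williams_index(comp_curve, obs_curves, denominator_form),
    error = function(e) NA_real_
  )
  ps <- percentage_statistic(list(computer = comp_curve,
                                  observers = obs_curves))
  od <- overlap_difference(comp_mask, mean_manual_region(obs_masks))
  structure(list(
    williams_index = wi,
    percentage_statistic = ps,
    overlapping_ratio = unname(od["OR"]),
    difference_ratio = unname(od["DR"]),
    ad_computer = vapply(obs_curves, function(o)
      average_distance(comp_curve, o), numeric(1)),
    n_observers = length(observers)
  ), class = "aphs_metrics")
}

#' @export
print.aphs_metrics <- function(x, ...) {
  cat("Boundary agreement vs", x$n_observers, "manual delineations\n")
  cat(sprintf("  modified Williams index: %.3f\n", x$williams_index))
  cat(sprintf("  percentage statistic:    %.2f%%\n", x$percentage_statistic))
  cat(sprintf("  overlapping ratio:       %.3f\n", x$overlapping_ratio))
  cat(sprintf("  difference ratio:        %.3f\n", x$difference_ratio))
  invisible(x)
}
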