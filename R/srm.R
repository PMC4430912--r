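# Statistical region merging (SRM).  A single pass over the 4-adjacent
# pixel couples sorted by gradient f = |I_p - I_p'|, merging the two
# incident regions whenever the statistical predicate holds.  Q controls
# the statistical complexity of the recovered structures: larger Q means
# a tighter merging bound and therefore more regions.

#' SRM parameters
#'
#' @param Q Statistical complexity parameter, `>= 1`.
#' @param g Number of gray levels (256 for 8-bit input).
#' @param bound Form of the merging bound `b(R)`:
#'   `"concentration"` (default) uses `b^2(R) = g^2 * ln(1/delta) / (2 Q |R|)`;
#'   `"nock"` uses the full bound
#'   `b^2(R) = g^2 * (min(g,|R|) ln(1+|R|) + ln(1/delta)) / (2 Q |R|)`.
#'   In both cases `delta = 1/(6 |I|^2)`.
#' @param delta Optional explicit confidence parameter in (0, 1); by default
#'   derived from the image size at run time.
#' @return An object of class `"srm_params"`.
#' @export
srm_params <- function(Q = 32, g = 256, bound = c("concentration", "nock"),
                       delta = NULL) {
  bound <- match.arg(bound)
  if (!is.numeric(Q) || length(Q) != 1L || Q < 1) stop("Q must be a number >= 1")
  if (!is.numeric(g) || g < 2) stop("g must be >= 2")
  if (!is.null(delta) && (delta <= 0 || delta >= 1)) {
    stop("delta must lie in (0, 1)")
  }
  structure(list(Q = Q, g = g, bound = bound, delta = delta),
            class = "srm_params")
}

# log(1/delta) with the default delta = 1/(6 |I|^2)
srm_log_inv_delta <- function(params, img_size) {
  if (!is.null(params$delta)) -log(params$delta) else log(6) + 2 * log(img_size)
}

# b^2(R) for a vector of region sizes
srm_b2 <- function(size, params, img_size) {
  lid <- srm_log_inv_delta(params, img_size)
  num <- switch(params$bound,
    concentration = lid,
    nock = pmin(params$g, size) * log1p(size) + lid
  )
  params$g^2 * num / (2 * params$Q * size)
}

#' SRM merging predicate
#'
#' Two regions merge when the difference of their intensity means is within
#' the statistical bound `sqrt(b^2(R) + b^2(R'))`.
#'
#' @param stats_R,stats_Rp Lists with elements `size` (pixel count) and
#'   `mean` (intensity mean).
#' @param params An [srm_params()] object.
#' @param img_size Total pixel count of the image (enters `delta`).
#' @return Logical.
#' @export
merge_predicate <- function(stats_R, stats_Rp, params, img_size) {
  if (stats_R$size < 1 || stats_Rp$size < 1) stop("regions must be non-empty")
  diff2 <- (stats_R$mean - stats_Rp$mean)^2
  diff2 <= srm_b2(stats_R$size, params, img_size) +
    srm_b2(stats_Rp$size, params, img_size)
}

#' Sort the 4-adjacent pixel couples of an image by gradient
#'
#' Couples are ordered by `f = |I_p - I_p'|` ascending; ties are broken by
#' the canonical raster order (row, then column, right neighbour before
#' down neighbour), so the traversal is bit-reproducible.
#'
#' @param img Intensity matrix.
#' @return A list with linear pixel indices `p1`, `p2` and gradients `f`,
#'   all sorted.
#' @export
sort_adjacent_pairs <- function(img) {
  img <- as_gray_image(img, g = Inf)
  ap <- adjacent_pairs(nrow(img), ncol(img))
  f <- abs(img[ap$p1] - img[ap$p2])
  o <- order(f, ap$key, method = "radix")
  list(p1 = ap$p1[o], p2 = ap$p2[o], f = f[o])
}

# Weighted union-find merging pass shared by the pixel-level SRM and the
# region-level merging used to coarsen a partition.  `size`/`sum` are the
# element statistics; pairs are visited in the given order and merged when
# the predicate holds on the pooled current statistics.
uf_merge_pass <- function(n, size, sum, p1, p2, params, img_size) {
  parent <- seq_len(n)
  c0 <- params$g^2 / (2 * params$Q)
  lid <- srm_log_inv_delta(params, img_size)
  nock <- params$bound == "nock"
  g <- params$g
  for (t in seq_along(p1)) {
    a <- p1[t]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- p2[t]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a == b) next
    na <- size[a]; nb <- size[b]
    dm <- sum[a] / na - sum[b] / nb
    if (nock) {
      b2 <- c0 * ((min(g, na) * log1p(na) + lid) / na +
                  (min(g, nb) * log1p(nb) + lid) / nb)
    } else {
      b2 <- c0 * lid * (1 / na + 1 / nb)
    }
    if (dm * dm <= b2) {
      if (na < nb) { tmp <- a; a <- b; b <- tmp }
      parent[b] <- a
      size[a] <- na + nb
      sum[a] <- sum[a] + sum[b]
    }
  }
  # final flatten
  repeat {
    nxt <- parent[parent]
    if (identical(nxt, parent)) break
    parent <- nxt
  }
  parent
}

# Relabel roots to contiguous ids 1..n_regions in order of first occurrence
relabel_contiguous <- function(roots) {
  match(roots, unique(roots))
}

#' Run statistical region merging
#'
#' @param img Intensity matrix.
#' @param params An [srm_params()] object (or a plain `Q` value).
#' @return An object of class `"aphs_partition"`: a list with `region`
#'   (integer matrix of ids `1..n_regions`), `n_regions`, and `stats`
#'   (data frame of region `size` and `mean`).
#' @export
run_srm <- function(img, params = srm_params()) {
  if (is.numeric(params)) params <- srm_params(Q = params)
  img <- as_gray_image(img, g = params$g)
  n <- length(img)
  sp <- sort_adjacent_pairs(img)
  roots <- uf_merge_pass(n, rep(1, n), as.numeric(img),
                         sp$p1, sp$p2, params, n)
  ids <- relabel_contiguous(roots)
  region <- matrix(ids, nrow(img), ncol(img))
  new_partition(region, img)
}

new_partition <- function(region, img) {
  ids <- as.integer(region)
  size <- tabulate(ids)
  mean <- as.vector(rowsum(as.numeric(img), ids)) / size
  structure(list(region = region, n_regions = max(region),
                 stats = data.frame(size = size, mean = mean)),
            class = "aphs_partition")
}

#' @export
print.aphs_partition <- function(x, ...) {
  cat(sprintf("SRM partition: %d x %d pixels, %d regions\n",
              nrow(x$region), ncol(x$region), x$n_regions))
  invisible(x)
}

# Coarsen a partition by region-level SRM at a (smaller) Q: the region
# adjacency pairs are sorted by |difference of means| (ties by id pair) and
# traversed once with the same predicate on pooled statistics.
region_merge <- function(part, params, img_size) {
  reg <- part$region
  ap <- adjacent_pairs(nrow(reg), ncol(reg))
  a <- reg[ap$p1]; b <- reg[ap$p2]
  cross <- a != b
  lo <- pmin(a[cross], b[cross]); hi <- pmax(a[cross], b[cross])
  key <- unique((lo - 1) * part$n_regions + hi)
  lo <- (key - 1) %/% part$n_regions + 1L
  hi <- (key - 1) %% part$n_regions + 1L
  dm <- abs(part$stats$mean[lo] - part$stats$mean[hi])
  o <- order(dm, lo, hi, method = "radix")
  roots <- uf_merge_pass(part$n_regions, part$stats$size,
                         part$stats$size * part$stats$mean,
                         lo[o], hi[o], params, img_size)
  map <- relabel_contiguous(roots)
  list(map = map, region = matrix(map[reg], nrow(reg), ncol(reg)))
}
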