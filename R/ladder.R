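# Multi-scale hierarchy: a ladder of strictly nested SRM partitions,
# the segmentation tree it induces (regions ordered by inclusion), and the
# ultrametric contour map encoding the whole hierarchy as one saliency
# value per interpixel edge.
#
# Level indexing convention: level 0 is the finest partition (largest Q),
# level lambda_1 is the root level where the whole ROI is one region.
# Nesting is guaranteed by construction: the finest level is pixel-level
# SRM at max(Q); each coarser level re-applies the merging predicate at the
# coarser Q to the previous level's region adjacency graph.

#' Build a nested ladder of segmentations
#'
#' @param img Intensity matrix.
#' @param q_values Ascending Q values, e.g. `2^(0:8)`.
#' @param bound,g Passed to [srm_params()].
#' @return An object of class `"aphs_ladder"`: `levels` is a list of
#'   `"aphs_partition"` objects ordered fine to coarse (the last one is the
#'   single-region root level), `maps[[k]]` sends region ids of level `k-1`
#'   to ids of level `k`, and `lambda1 = length(levels) - 1`.
#' @export
build_nested_ladder <- function(img, q_values = 2^(0:8),
                                bound = "concentration", g = 256) {
  if (length(q_values) < 1L) stop("q_values must contain at least one Q")
  if (is.unsorted(q_values, strictly = TRUE)) {
    stop("q_values must be strictly ascending")
  }
  img <- as_gray_image(img, g = g)
  n <- length(img)
  qs <- rev(q_values)   # construction order: fine (large Q) to coarse
  levels <- vector("list", length(qs) + 1L)
  maps <- vector("list", length(qs))
  levels[[1L]] <- run_srm(img, srm_params(Q = qs[1L], g = g, bound = bound))
  if (length(qs) > 1L) {
    for (k in 2:length(qs)) {
      rm <- region_merge(levels[[k - 1L]],
                         srm_params(Q = qs[k], g = g, bound = bound), n)
      maps[[k - 1L]] <- rm$map
      levels[[k]] <- new_partition(rm$region, img)
    }
  }
  # root level: the whole ROI (Omega) as a single region
  top <- length(qs)
  maps[[top]] <- rep(1L, levels[[top]]$n_regions)
  levels[[top + 1L]] <- new_partition(
    matrix(1L, nrow(img), ncol(img)), img)
  structure(list(q_values = q_values, levels = levels, maps = maps,
                 lambda1 = length(levels) - 1L, img = img),
            class = "aphs_ladder")
}

#' @export
print.aphs_ladder <- function(x, ...) {
  cat(sprintf("Nested segmentation ladder: %d levels (lambda_1 = %d), Q = %s\n",
              length(x$levels), x$lambda1,
              paste(x$q_values, collapse = ", ")))
  cat("regions per level (fine to coarse):",
      paste(vapply(x$levels, function(p) p$n_regions, integer(1)),
            collapse = ", "), "\n")
  invisible(x)
}

# id of the level-`lambda` region containing each finest region
finest_to_level <- function(ladder, lambda) {
  ids <- seq_len(ladder$levels[[1L]]$n_regions)
  if (lambda >= 1L) for (k in seq_len(lambda)) ids <- ladder$maps[[k]][ids]
  ids
}

# check strict nesting by pixel containment (used by tests and build_tree)
validate_ladder <- function(ladder) {
  for (k in seq_along(ladder$maps)) {
    fine <- ladder$levels[[k]]$region
    coarse <- ladder$levels[[k + 1L]]$region
    if (!identical(as.integer(ladder$maps[[k]][fine]), as.integer(coarse))) {
      stop("ladder is not nested at level ", k)
    }
  }
  invisible(TRUE)
}

#' Build the segmentation tree of a nested ladder
#'
#' One node per maximal region across its lifetime: a region persisting
#' unchanged over several levels is a single node with a birth and death
#' level.  Leaves are the finest regions; the root is the whole ROI.
#' Node ids are assigned leaves first, so a node's parent always has a
#' larger id than the node itself.
#'
#' @param ladder An `"aphs_ladder"`.
#' @return An object of class `"aphs_tree"` with fields `parent` (NA for the
#'   root), `children`, `birth`, `death`, `size`, `members` (finest region
#'   ids per node), `leaves`, `root`, `n_nodes`, `n_levels`.
#' @export
build_tree <- function(ladder) {
  validate_ladder(ladder)
  n0 <- ladder$levels[[1L]]$n_regions
  parent <- rep(NA_integer_, n0)
  birth <- rep(0L, n0)
  death <- rep(0L, n0)
  members <- as.list(seq_len(n0))
  node_of <- seq_len(n0)           # node id of each current-level region
  for (lam in seq_len(ladder$lambda1)) {
    map <- ladder$maps[[lam]]
    ncoarse <- max(map)
    new_node_of <- integer(ncoarse)
    kids_by_coarse <- split(node_of, map)
    for (cid in seq_len(ncoarse)) {
      kids <- unique(kids_by_coarse[[cid]])
      if (length(kids) == 1L) {
        death[kids] <- lam
        new_node_of[cid] <- kids
      } else {
        nid <- length(parent) + 1L
        parent[kids] <- nid
        parent[nid] <- NA_integer_
        birth[nid] <- lam
        death[nid] <- lam
        members[[nid]] <- sort(unlist(members[kids], use.names = FALSE))
        new_node_of[cid] <- nid
      }
    }
    node_of <- new_node_of
  }
  n_nodes <- length(parent)
  children <- vector("list", n_nodes)
  for (i in which(!is.na(parent))) {
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  leaf_size <- ladder$levels[[1L]]$stats$size
  size <- vapply(members, function(m) sum(leaf_size[m]), numeric(1))
  structure(list(parent = parent, children = children, birth = birth,
                 death = death, size = size, members = members,
                 leaves = seq_len(n0), root = node_of[1L],
                 n_nodes = n_nodes, n_levels = ladder$lambda1,
                 finest = ladder$levels[[1L]]),
            class = "aphs_tree")
}

#' @export
print.aphs_tree <- function(x, ...) {
  cat(sprintf("Segmentation tree: %d nodes (%d leaves), %d levels\n",
              x$n_nodes, length(x$leaves), x$n_levels))
  invisible(x)
}

#' Compute the ultrametric contour map of a nested ladder
#'
#' Each 4-adjacent interpixel edge gets the smallest level index at which
#' its two sides belong to the same region (the scale at which the
#' separating contour vanishes).  Edges interior to a finest region have
#' saliency 0; contours surviving to the top carry `lambda_1`.
#'
#' @param ladder An `"aphs_ladder"`.
#' @return An object of class `"aphs_ucm"` with per-edge endpoints `p1`,
#'   `p2` (linear pixel indices), integer `saliency`, `lambda1` and `dim`.
#' @export
compute_ucm <- function(ladder) {
  reg0 <- ladder$levels[[1L]]$region
  ap <- adjacent_pairs(nrow(reg0), ncol(reg0))
  a0 <- reg0[ap$p1]; b0 <- reg0[ap$p2]
  sal <- integer(length(a0))               # 0 where same finest region
  open <- which(a0 != b0)
  for (lam in seq_len(ladder$lambda1)) {
    if (!length(open)) break
    ids <- finest_to_level(ladder, lam)
    merged <- ids[a0[open]] == ids[b0[open]]
    sal[open[merged]] <- lam
    open <- open[!merged]
  }
  structure(list(p1 = ap$p1, p2 = ap$p2, saliency = sal,
                 lambda1 = ladder$lambda1, dim = dim(reg0),
                 img = ladder$img),
            class = "aphs_ucm")
}

#' @export
print.aphs_ucm <- function(x, ...) {
  cat(sprintf("Ultrametric contour map: %d x %d pixels, lambda_1 = %d, %d boundary edges\n",
              x$dim[1], x$dim[2], x$lambda1, sum(x$saliency > 0)))
  invisible(x)
}

#' Threshold an ultrametric contour map
#'
#' Connected components of pixels not separated by any edge whose saliency
#' exceeds `level`; by ultrametricity this reproduces the ladder's
#' partition at that level exactly.
#'
#' @param ucm An `"aphs_ucm"`.
#' @param level Integer level in `[0, lambda_1]`.
#' @return An `"aphs_partition"`.
#' @export
threshold_ucm <- function(ucm, level) {
  if (level < 0 || level > ucm$lambda1) {
    stop("level must lie in [0, lambda_1]")
  }
  n <- prod(ucm$dim)
  keep <- ucm$saliency <= level
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ucm$p1[keep], ucm$p2[keep]))
  memb <- igraph::components(g)$membership
  ids <- match(memb, unique(memb))
  new_partition(matrix(ids, ucm$dim[1], ucm$dim[2]), ucm$img)
}

#' Render a UCM as a double-resolution raster
#'
#' Interpixel edges are drawn on a `(2H+1) x (2W+1)` grid so contours are
#' one raster cell wide; values are the integer saliencies (0 inside
#' regions), optionally rescaled to `[0, 1]` for PNG export.
#'
#' @param ucm An `"aphs_ucm"`.
#' @param rescale Divide by `lambda_1` so values lie in `[0, 1]`.
#' @return Numeric matrix of size `(2H+1) x (2W+1)`.
#' @export
ucm_raster <- function(ucm, rescale = TRUE) {
  H <- ucm$dim[1]; W <- ucm$dim[2]
  out <- matrix(0, 2 * H + 1, 2 * W + 1)
  r1 <- (ucm$p1 - 1L) %% H + 1L; c1 <- (ucm$p1 - 1L) %/% H + 1L
  r2 <- (ucm$p2 - 1L) %% H + 1L; c2 <- (ucm$p2 - 1L) %/% H + 1L
  er <- r1 + r2; ec <- c1 + c2          # midpoint on the doubled grid
  pos <- cbind(er, ec)
  out[pos] <- ucm$saliency
  # edge crossings (odd,odd corners) take the max of incident edge saliencies
  for (dr in c(-1L, 1L)) for (dc in c(-1L, 1L)) {
    corner <- cbind(er + ifelse(er %% 2 == 0, dr, 0L),
                    ec + ifelse(ec %% 2 == 0, dc, 0L))
    ok <- corner[, 1] >= 1 & corner[, 1] <= 2 * H + 1 &
      corner[, 2] >= 1 & corner[, 2] <= 2 * W + 1 &
      (corner[, 1] %% 2 == 1) & (corner[, 2] %% 2 == 1)
    out[corner[ok, , drop = FALSE]] <-
      pmax(out[corner[ok, , drop = FALSE]], ucm$saliency[ok])
  }
  if (rescale && ucm$lambda1 > 0) out <- out / ucm$lambda1
  out
}

#' Export a segmentation tree as JSON
#'
#' @param tree An `"aphs_tree"`.
#' @param path Output path.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(seq_len(tree$n_nodes), function(i) {
    list(id = i,
         parent = if (is.na(tree$parent[i])) NULL else tree$parent[i],
         children = tree$children[[i]],
         birth_level = tree$birth[i], death_level = tree$death[i],
         size = tree$size[i])
  })
  jsonlite::write_json(list(n_nodes = tree$n_nodes, root = tree$root,
                            leaves = tree$leaves, nodes = nodes),
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Export / import a UCM as a lossless edge-list TSV
#'
#' Columns `p1`, `p2` (linear pixel indices) and integer `saliency`;
#' a header line carries the image dimensions and `lambda_1`.
#' @param ucm An `"aphs_ucm"`.
#' @param path Output path.
#' @export
write_ucm_edges <- function(ucm, path) {
  con <- file(path, "w")
  writeLines(sprintf("# dim %d %d lambda1 %d",
                     ucm$dim[1], ucm$dim[2], ucm$lambda1), con)
  write.table(data.frame(p1 = ucm$p1, p2 = ucm$p2, saliency = ucm$saliency),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_ucm_edges
#' @export
read_ucm_edges <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  df <- utils::read.table(path, header = TRUE, skip = 1, sep = "\t")
  structure(list(p1 = df$p1, p2 = df$p2, saliency = df$saliency,
                 lambda1 = as.integer(hdr[6]),
                 dim = as.integer(hdr[3:4]), img = NULL),
            class = "aphs_ucm")
}
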