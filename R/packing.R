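# Anatomy packing: label assignment over the segmentation tree by
# minimizing the CRF energy E = U + V subject to the completeness
# constraint (every pixel covered by exactly one labeled segment) and the
# non-overlap constraint (no two segments on a root-to-leaf path both
# labeled).  For K = 2 the problem is solved exactly by a single min-cut
# over a tree-structured (pylon) graph; for K > 2 alpha-expansion performs
# a series of such binary cuts.
#
# Binary encoding used by the cut: per tree node i two binary variables,
#   A_i = 1  iff i is at or below a segment selected with the "A" option,
#   B_i = 1  iff i is at or below a segment selected with the "B" option.
# A and B propagate down the tree, are mutually exclusive, and every leaf
# carries exactly one of them; the selected segments are the maximal
# A-nodes and maximal B-nodes, charged their unary cost on the edge to
# their parent.  All terms are submodular, so a single max-flow solves the
# relaxation exactly.

#' CRF energy parameters
#'
#' @param gamma Pairwise weight `>= 0` (cost per boundary pixel pair with
#'   differing labels, modulated by contrast).
#' @param beta Contrast scale in the kernel `exp(-beta * dI^2)`; `"auto"`
#'   sets `1 / (2 * mean(dI^2))` over all 4-adjacent pairs of the image.
#' @param K Number of semantic labels.
#' @return Object of class `"energy_params"`.
#' @export
energy_params <- function(gamma = 50, beta = "auto", K = 2) {
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta < 0)) {
    stop("beta must be 'auto' or a nonnegative number")
  }
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0")
  if (K < 2) stop("K must be >= 2")
  structure(list(gamma = gamma, beta = beta, K = K), class = "energy_params")
}

resolve_beta <- function(beta, img) {
  if (!identical(beta, "auto")) return(beta)
  ap <- adjacent_pairs(nrow(img), ncol(img))
  msq <- mean((img[ap$p1] - img[ap$p2])^2)
  if (msq == 0) 0 else 1 / (2 * msq)
}

#' Unary cost of assigning a label to a tree segment
#'
#' The per-pixel negative log-likelihood under the label's intensity
#' histogram, summed over the segment's pixels; assigning label 0 (not
#' selected) costs nothing.
#'
#' @param tree An `"aphs_tree"`.
#' @param node Node id.
#' @param label Label in `1..K` (or 0).
#' @param img Intensity matrix.
#' @param model An `"aphs_histmodel"`.
#' @return Cost (nonnegative; histogram smoothing keeps logs finite).
#' @export
unary_cost <- function(tree, node, label, img, model) {
  if (label == 0) return(0)
  px <- which(tree$finest$region %in% tree$members[[node]])
  bins <- intensity_bins(img[px], model)
  sum(-log(model$h[cbind(bins, label)]))
}

# N x K matrix of unary costs for all nodes, via per-leaf bin counts
node_unaries <- function(tree, img, model) {
  bins <- intensity_bins(as.numeric(img), model)
  counts <- rowsum(diag(model$bins)[bins, , drop = FALSE],
                   as.integer(tree$finest$region))
  leafU <- counts %*% (-log(model$h))       # n_leaves x K
  U <- matrix(0, tree$n_nodes, ncol(model$h))
  for (i in seq_len(tree$n_nodes)) {
    U[i, ] <- colSums(leafU[tree$members[[i]], , drop = FALSE])
  }
  U
}

# pairwise Potts weights aggregated per adjacent leaf pair
leaf_edge_weights <- function(img, partition, gamma, beta) {
  ap <- adjacent_pairs(nrow(img), ncol(img))
  a <- partition$region[ap$p1]; b <- partition$region[ap$p2]
  cross <- a != b
  if (!any(cross)) {
    return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  }
  dI2 <- (img[ap$p1[cross]] - img[ap$p2[cross]])^2
  w <- gamma * exp(-beta * dI2)
  lo <- pmin(a[cross], b[cross]); hi <- pmax(a[cross], b[cross])
  key <- (lo - 1) * partition$n_regions + hi
  agg <- rowsum(w, key)
  k <- as.numeric(rownames(agg))
  data.frame(i = (k - 1) %/% partition$n_regions + 1,
             j = (k - 1) %% partition$n_regions + 1,
             w = as.numeric(agg))
}

#' Pairwise (boundary) cost of a pixel label map
#'
#' Sum over 4-adjacent pixel pairs with differing labels of
#' `gamma * exp(-beta * (I_i - I_j)^2)`.
#'
#' @param img Intensity matrix.
#' @param labelmap Integer label matrix of the same size.
#' @param params An [energy_params()].
#' @return Cost.
#' @export
pairwise_cost <- function(img, labelmap, params) {
  beta <- resolve_beta(params$beta, img)
  ap <- adjacent_pairs(nrow(img), ncol(img))
  diff <- labelmap[ap$p1] != labelmap[ap$p2]
  sum(params$gamma * exp(-beta * (img[ap$p1[diff]] - img[ap$p2[diff]])^2))
}

# label of the selected ancestor-or-self of each node (NA above selection);
# exploits node ids increasing from leaves to root
ancestor_labels <- function(tree, y) {
  anc <- rep(NA_integer_, tree$n_nodes)
  for (i in tree$n_nodes:1) {
    anc[i] <- if (y[i] > 0) y[i]
      else if (!is.na(tree$parent[i])) anc[tree$parent[i]]
      else NA_integer_
  }
  anc
}

#' Check the completeness and non-overlap constraints of a labeling
#'
#' @param tree An `"aphs_tree"`.
#' @param y Integer vector: label per node (0 = not selected).
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_labeling <- function(tree, y) {
  if (length(y) != tree$n_nodes) stop("labeling length does not match tree")
  sel <- y > 0
  # non-overlap: no selected node may have a selected strict ancestor
  anc_sel <- rep(FALSE, tree$n_nodes)
  for (i in tree$n_nodes:1) {
    p <- tree$parent[i]
    if (!is.na(p)) anc_sel[i] <- anc_sel[p] || sel[p]
  }
  if (any(sel & anc_sel)) {
    stop("non-overlap violated: nested segments both selected")
  }
  if (anyNA(ancestor_labels(tree, y)[tree$leaves])) {
    stop("completeness violated: some pixels are covered by no labeled segment")
  }
  invisible(TRUE)
}

#' Realize a labeling as a pixel label map
#'
#' @param tree An `"aphs_tree"`.
#' @param y Valid labeling vector.
#' @return Integer matrix: each pixel takes the label of its unique
#'   selected ancestor segment.
#' @export
labeling_to_pixelmap <- function(tree, y) {
  validate_labeling(tree, y)
  leaf_lab <- ancestor_labels(tree, y)[tree$leaves]
  reg <- tree$finest$region
  matrix(leaf_lab[reg], nrow(reg), ncol(reg))
}

#' Total CRF energy of a labeling
#'
#' @param tree An `"aphs_tree"`.
#' @param y Labeling vector (validated against the constraints).
#' @param img Intensity matrix.
#' @param model An `"aphs_histmodel"`.
#' @param params An [energy_params()].
#' @return `U + V`.
#' @export
total_energy <- function(tree, y, img, model, params) {
  validate_labeling(tree, y)
  U <- node_unaries(tree, img, model)
  sel <- which(y > 0)
  sum(U[cbind(sel, y[sel])]) + pairwise_cost(img, labeling_to_pixelmap(tree, y), params)
}

# energy from precomputed unaries and leaf-pair weights (internal fast path)
labeling_energy <- function(tree, y, U, edges) {
  sel <- which(y > 0)
  e <- sum(U[cbind(sel, y[sel])])
  if (nrow(edges)) {
    lab <- ancestor_labels(tree, y)
    e <- e + sum(edges$w[lab[edges$i] != lab[edges$j]])
  }
  e
}

# ---- the binary tree-cut engine -------------------------------------------
# costA/costB: cost of being the maximal A- / B-node (Inf forbids the
# option entirely for that node); forbidB: nodes where B itself (not just
# B-maximal) is impossible; tables: per adjacent-leaf-pair 2x2 energies on
# the leaves' A indicators, columns e00, e01, e10, e11 (exy = cost when
# (A_i = x, A_j = y)).
tree_cut <- function(tree, costA, costB, tables,
                     forbidB = rep(FALSE, tree$n_nodes)) {
  N <- tree$n_nodes
  finite_sum <- sum(costA[is.finite(costA)]) + sum(costB[is.finite(costB)]) +
    sum(tables$e00 + tables$e01 + tables$e10 + tables$e11) + 1
  M <- max(finite_sum, 1) * 4
  costA <- pmin(costA, M); costB <- pmin(costB, M)
  # vertex layout: 1 = source, 2 = sink, A_i = 2 + i, B'_i = 2 + N + i
  vA <- function(i) 2L + i
  vB <- function(i) 2L + N + i
  u1 <- numeric(2L + 2L * N)   # cost when variable = 1 (source side)
  u0 <- numeric(2L + 2L * N)
  ef <- integer(0); et <- integer(0); ec <- numeric(0)
  add_pair <- function(x, y, e00, e01, e10, e11) {
    # E(x, y); submodular: e01 + e10 >= e00 + e11
    cap <- e01 + e10 - e00 - e11
    u1[x] <<- u1[x] + (e10 - e00)
    u1[y] <<- u1[y] + (e11 - e10)
    # the residual e00 is a constant shared by all configurations: dropped
    if (cap > 0) {
      ef <<- c(ef, y); et <<- c(et, x); ec <<- c(ec, cap)
    } else if (cap < -1e-9) stop("non-submodular pairwise term")
  }
  root <- tree$root
  for (i in seq_len(N)) {
    p <- tree$parent[i]
    if (!is.na(p)) {
      # A: forbid (A_i = 0, A_p = 1); charge costA[i] at the maximal A node
      add_pair(vA(i), vA(p), 0, M, costA[i], 0)
      # B' : forbid (B'_i = 1, B'_p = 0); charge costB[i] when B-maximal,
      # i.e. (B'_i = 0, B'_p = 1)
      add_pair(vB(i), vB(p), 0, costB[i], M, 0)
    }
    # exclusion: A_i = 1 and B_i = 1 (B'_i = 0) never together
    is_leaf <- i <= length(tree$leaves)
    add_pair(vA(i), vB(i), 0, if (is_leaf) M else 0, M, 0)
    if (forbidB[i]) u0[vB(i)] <- u0[vB(i)] + M
  }
  u1[vA(root)] <- u1[vA(root)] + costA[root]
  u0[vB(root)] <- u0[vB(root)] + costB[root]
  if (nrow(tables)) {
    for (t in seq_len(nrow(tables))) {
      add_pair(vA(tables$i[t]), vA(tables$j[t]),
               tables$e00[t], tables$e01[t], tables$e10[t], tables$e11[t])
    }
  }
  # unary terms -> terminal edges
  d <- u1 - u0
  pos <- which(d > 0)
  ef <- c(ef, pos); et <- c(et, rep(2L, length(pos))); ec <- c(ec, d[pos])
  neg <- which(d < 0)
  ef <- c(ef, rep(1L, length(neg))); et <- c(et, neg); ec <- c(ec, -d[neg])
  # aggregate parallel edges
  key <- paste(ef, et)
  agg <- rowsum(ec, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  from <- as.integer(vapply(parts, `[`, "", 1L))
  to <- as.integer(vapply(parts, `[`, "", 2L))
  g <- igraph::make_empty_graph(2L + 2L * N, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  fl <- igraph::max_flow(g, source = 1, target = 2,
                         capacity = as.numeric(agg))
  src_side <- rep(FALSE, 2L + 2L * N)
  src_side[as.integer(fl$partition1)] <- TRUE
  if (!src_side[1L] || src_side[2L]) {  # orientation safety
    src_side <- !src_side
  }
  A <- src_side[vA(seq_len(N))]
  B <- !src_side[vB(seq_len(N))]
  list(A = A, B = B)
}

# decode maximal A/B nodes into a labeling
decode_cut <- function(tree, cut, labA, labB) {
  y <- integer(tree$n_nodes)
  for (i in seq_len(tree$n_nodes)) {
    p <- tree$parent[i]
    topA <- cut$A[i] && (is.na(p) || !cut$A[p])
    topB <- cut$B[i] && (is.na(p) || !cut$B[p])
    if (topA) y[i] <- labA else if (topB) y[i] <- labB[i]
  }
  y
}

#' Exact two-label inference over the segmentation tree
#'
#' Globally minimizes the CRF energy over all labelings satisfying the
#' completeness and non-overlap constraints, for K = 2, by one min-cut on
#' the tree-structured graph.
#'
#' @param tree An `"aphs_tree"`.
#' @param U `n_nodes x 2` matrix of unary costs.
#' @param edges Data frame of adjacent-leaf pairwise weights
#'   (`i`, `j` leaf node ids, `w >= 0`), e.g. from the image contrast
#'   kernel.
#' @return Integer labeling vector (values 0, 1, 2) attaining the global
#'   minimum.
#' @export
solve_binary_pylon <- function(tree, U, edges = data.frame(i = integer(0),
                                                           j = integer(0),
                                                           w = numeric(0))) {
  if (tree$n_nodes < 1) stop("empty tree")
  stopifnot(ncol(U) == 2)
  z <- numeric(nrow(edges))
  tables <- data.frame(i = edges$i, j = edges$j,
                       e00 = z, e01 = edges$w, e10 = edges$w, e11 = z)
  cut <- tree_cut(tree, U[, 1], U[, 2], tables)
  y <- decode_cut(tree, cut, 1L, rep(2L, tree$n_nodes))
  validate_labeling(tree, y)
  y
}

#' Multi-label inference by alpha-expansion over the tree
#'
#' Starts from the whole ROI carrying the single cheapest label and
#' repeatedly solves binary expansion moves (current labeling vs label
#' alpha) with the exact tree cut, accepting a move only when the energy
#' strictly decreases; terminates when a full sweep over `1..K` changes
#' nothing, or after `max_sweeps` sweeps.
#'
#' @param tree An `"aphs_tree"`.
#' @param U `n_nodes x K` unary cost matrix.
#' @param edges Adjacent-leaf pairwise weights (see
#'   [solve_binary_pylon()]).
#' @param K Number of labels.
#' @param max_sweeps Sweep cap.
#' @return List with the labeling `y`, the `energy` trace (initial energy
#'   followed by the energy after each accepted move), and `sweeps` used.
#' @export
solve_multilabel <- function(tree, U, edges, K = ncol(U), max_sweeps = 10) {
  y <- integer(tree$n_nodes)
  if (all(is.finite(U))) {
    y[tree$root] <- which.min(U[tree$root, ])
  } else {
    # hard-pinned leaves of different classes make any whole-ROI start
    # infeasible (and can deadlock single-label expansion moves): start
    # from every leaf selected with its cheapest admissible label instead
    y[tree$leaves] <- apply(U[tree$leaves, , drop = FALSE], 1, which.min)
  }
  e_cur <- labeling_energy(tree, y, U, edges)
  trace <- e_cur
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (alpha in seq_len(K)) {
      anc <- ancestor_labels(tree, y)
      forbidB <- is.na(anc)
      costB <- ifelse(forbidB, 0, U[cbind(seq_len(tree$n_nodes),
                                          ifelse(forbidB, 1L, anc))])
      tables <- if (nrow(edges)) {
        lp <- anc[edges$i]; lq <- anc[edges$j]
        data.frame(i = edges$i, j = edges$j,
                   e00 = edges$w * (lp != lq),
                   e01 = edges$w * (lp != alpha),
                   e10 = edges$w * (alpha != lq),
                   e11 = 0)
      } else {
        data.frame(i = integer(0), j = integer(0),
                   e00 = numeric(0), e01 = numeric(0),
                   e10 = numeric(0), e11 = numeric(0))
      }
      cut <- tree_cut(tree, U[, alpha], costB, tables, forbidB)
      y_new <- decode_cut(tree, cut, as.integer(alpha), anc)
      validate_labeling(tree, y_new)
      e_new <- labeling_energy(tree, y_new, U, edges)
      if (e_new < e_cur - 1e-9) {
        y <- y_new
        e_cur <- e_new
        trace <- c(trace, e_new)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(y = y, energy = trace, sweeps = sweep)
}
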