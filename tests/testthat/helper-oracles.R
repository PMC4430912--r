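# Independent oracles for the tree-constrained inference: a random-tree
# generator, exhaustive enumeration of all labelings satisfying the
# completeness and non-overlap constraints, and a from-scratch energy
# evaluator (ancestor walk per leaf, no shared code with the solver path).

random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  parent <- rep(NA_integer_, n_leaves)
  roots <- seq_len(n_leaves)
  while (length(roots) > 1) {
    k <- min(length(roots), sample(2:3, 1))
    pick <- sample(roots, k)
    nid <- length(parent) + 1L
    parent[pick] <- nid
    parent[nid] <- NA_integer_
    roots <- c(setdiff(roots, pick), nid)
  }
  n <- length(parent)
  children <- vector("list", n)
  for (i in which(!is.na(parent))) {
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  members <- vector("list", n)
  for (i in seq_len(n)) {
    members[[i]] <- if (i <= n_leaves) i else
      sort(unlist(members[children[[i]]]))
  }
  structure(list(parent = parent, children = children,
                 birth = rep(0L, n), death = rep(0L, n),
                 size = lengths(members), members = members,
                 leaves = seq_len(n_leaves), root = n, n_nodes = n,
                 n_levels = 1L, finest = NULL), class = "aphs_tree")
}

random_costs <- function(tree, K, seed, n_edges = NULL) {
  set.seed(seed)
  nl <- length(tree$leaves)
  U <- matrix(runif(tree$n_nodes * K, 0, 10), tree$n_nodes, K)
  all_pairs <- if (nl >= 2) t(utils::combn(nl, 2)) else
    matrix(integer(0), 0, 2)
  if (is.null(n_edges)) n_edges <- sample(0:min(10, nrow(all_pairs)), 1)
  edges <- if (n_edges > 0) {
    pr <- all_pairs[sample(nrow(all_pairs), n_edges), , drop = FALSE]
    data.frame(i = pr[, 1], j = pr[, 2], w = runif(n_edges, 0, 5))
  } else {
    data.frame(i = integer(0), j = integer(0), w = numeric(0))
  }
  list(U = U, edges = edges)
}

# every labeling: each node is either selected (K label choices, covering
# its whole subtree) or defers to its children
enum_labelings <- function(tree, K) {
  rec <- function(node) {
    res <- lapply(seq_len(K), function(k) {
      y <- integer(tree$n_nodes); y[node] <- k; y
    })
    kids <- tree$children[[node]]
    if (length(kids)) {
      combo <- rec(kids[[1]])
      for (kid in kids[-1]) {
        sub <- rec(kid)
        combo <- unlist(lapply(combo, function(a)
          lapply(sub, function(b) a + b)), recursive = FALSE)
      }
      res <- c(res, combo)
    }
    res
  }
  rec(tree$root)
}

brute_energy <- function(tree, y, U, edges) {
  lab <- function(i) { while (y[i] == 0) i <- tree$parent[i]; y[i] }
  e <- sum(U[cbind(which(y > 0), y[y > 0])])
  if (nrow(edges)) for (t in seq_len(nrow(edges))) {
    if (lab(edges$i[t]) != lab(edges$j[t])) e <- e + edges$w[t]
  }
  e
}

brute_minimum <- function(tree, U, edges, K) {
  min(vapply(enum_labelings(tree, K), brute_energy, numeric(1),
             tree = tree, U = U, edges = edges))
}

# default small seed rasters for the two-level disk phantom
two_class_seeds <- function(size) {
  seeds <- matrix(0L, size, size)
  seeds[2, 2] <- 1L
  seeds[round(size / 2), round(size / 2)] <- 2L
  seeds
}
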