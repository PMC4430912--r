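# Tree-constrained CRF: unary/pairwise costs, the exact binary cut, and
# alpha-expansion. Exactness is checked against exhaustive enumeration of
# all valid labelings with an independent energy evaluator
# (helper-oracles.R).

two_region_fit <- function() {
  img <- matrix(0, 12, 12); img[, 7:12] <- 255
  ladder <- build_nested_ladder(img, c(1, 64))
  list(img = img, ladder = ladder, tree = build_tree(ladder))
}

test_that("unary costs match the log-likelihood formula and are additive", {
  x <- two_region_fit()
  seeds <- matrix(0L, 12, 12); seeds[2, 2] <- 1L; seeds[2, 10] <- 2L
  m <- build_histograms(x$img, seeds, bins = 4, epsilon = 1e-6)
  # scalar oracle: leaf of 72 dark pixels, all in bin 1
  h11 <- m$h[1, 1]
  dark_leaf <- x$tree$finest$region[1, 1]
  expect_equal(unary_cost(x$tree, dark_leaf, 1, x$img, m), 72 * -log(h11))
  # label 0 (unselected) costs nothing
  expect_equal(unary_cost(x$tree, x$tree$root, 0, x$img, m), 0)
  # additivity over the tree: cost(parent) = sum over children
  U <- node_unaries(x$tree, x$img, m)
  for (i in seq_len(x$tree$n_nodes)) {
    kids <- x$tree$children[[i]]
    if (length(kids)) {
      expect_equal(U[i, ], colSums(U[kids, , drop = FALSE]))
    }
    # and node_unaries agrees with the per-node function
    for (k in 1:2) {
      expect_equal(U[i, k], unary_cost(x$tree, i, k, x$img, m))
    }
  }
})

test_that("pairwise cost matches a hand-computed contrast kernel", {
  img <- matrix(c(0, 0, 100, 100), 2, 2)
  lab <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  p <- energy_params(gamma = 10, beta = 0.0001)
  # two horizontal cross-label pairs, each with dI = 100
  expect_equal(pairwise_cost(img, lab, p), 2 * 10 * exp(-0.0001 * 100^2))
  # identical labels: zero
  expect_equal(pairwise_cost(img, matrix(1L, 2, 2), p), 0)
  # beta = 0 reduces to gamma per cross pair
  expect_equal(pairwise_cost(img, lab, energy_params(gamma = 3, beta = 0)), 6)
  # auto beta: 1 / (2 * mean dI^2) over all 4-adjacencies
  expect_equal(resolve_beta("auto", img), 1 / (2 * mean(c(0, 0, 100, 100)^2)))
  expect_equal(resolve_beta("auto", matrix(5, 3, 3)), 0)
  expect_error(energy_params(gamma = -1), "gamma")
  expect_error(energy_params(beta = -2), "beta")
})

test_that("labeling validation enforces completeness and non-overlap", {
  x <- two_region_fit()
  tr <- x$tree                       # 3 nodes: 2 leaves + root
  expect_true(validate_labeling(tr, c(0L, 0L, 1L)))
  expect_true(validate_labeling(tr, c(1L, 2L, 0L)))
  expect_error(validate_labeling(tr, c(1L, 0L, 2L)), "non-overlap")
  expect_error(validate_labeling(tr, c(1L, 0L, 0L)), "completeness")
  expect_error(validate_labeling(tr, c(1L, 2L)), "length")
  # pixel maps realize the selected segments
  pm <- labeling_to_pixelmap(tr, c(0L, 0L, 2L))
  expect_true(all(pm == 2L))
  pm2 <- labeling_to_pixelmap(tr, c(1L, 2L, 0L))
  expect_equal(sort(unique(as.integer(pm2))), 1:2)
  expect_equal(as.integer(table(pm2)), c(72L, 72L))
})

test_that("total energy equals unary plus boundary terms", {
  x <- two_region_fit()
  seeds <- matrix(0L, 12, 12); seeds[2, 2] <- 1L; seeds[2, 10] <- 2L
  m <- build_histograms(x$img, seeds, bins = 4)
  p <- energy_params(gamma = 7, beta = 0)
  U <- node_unaries(x$tree, x$img, m)
  y <- c(1L, 2L, 0L)
  # 12 cross-label pixel pairs along the vertical boundary, beta = 0
  expect_equal(total_energy(x$tree, y, x$img, m, p),
               U[1, 1] + U[2, 2] + 7 * 12)
  # whole-ROI selection has no boundary term
  expect_equal(total_energy(x$tree, c(0L, 0L, 1L), x$img, m, p), U[3, 1])
})

test_that("a single-node tree takes the cheaper label", {
  tr <- random_tree(1, seed = 1)
  expect_equal(solve_binary_pylon(tr, matrix(c(5, 1), 1, 2)), 2L)
  expect_equal(solve_binary_pylon(tr, matrix(c(0.5, 3), 1, 2)), 1L)
})

test_that("the binary cut is exact on random trees (vs enumeration)", {
  for (seed in 1:25) {
    tr <- random_tree(sample(2:9, 1), seed = seed)
    rc <- random_costs(tr, 2, seed = seed + 1000)
    y <- solve_binary_pylon(tr, rc$U, rc$edges)
    expect_true(validate_labeling(tr, y))
    expect_equal(brute_energy(tr, y, rc$U, rc$edges),
                 brute_minimum(tr, rc$U, rc$edges, 2),
                 tolerance = 1e-9)
  }
})

test_that("infinite unary costs act as hard exclusions in the cut", {
  tr <- random_tree(4, seed = 7)
  rc <- random_costs(tr, 2, seed = 8, n_edges = 3)
  U <- rc$U
  U[tr$leaves, 1] <- Inf            # label 1 forbidden on every leaf
  y <- solve_binary_pylon(tr, U, rc$edges)
  lab <- aphs:::ancestor_labels(tr, y)
  expect_true(all(lab[tr$leaves] == 2L))
})

test_that("without pairwise terms the optimum is the cheapest tree packing", {
  # gamma = 0: compare against brute force with K = 3 labels
  for (seed in 1:10) {
    tr <- random_tree(sample(2:7, 1), seed = seed + 50)
    rc <- random_costs(tr, 3, seed = seed + 60, n_edges = 0)
    sol <- solve_multilabel(tr, rc$U, rc$edges, K = 3)
    expect_equal(brute_energy(tr, sol$y, rc$U, rc$edges),
                 brute_minimum(tr, rc$U, rc$edges, 3),
                 tolerance = 1e-9)
  }
})

test_that("alpha-expansion with K = 2 reaches the exact binary minimum", {
  for (seed in 1:15) {
    tr <- random_tree(sample(2:8, 1), seed = seed + 200)
    rc <- random_costs(tr, 2, seed = seed + 300)
    y_exact <- solve_binary_pylon(tr, rc$U, rc$edges)
    sol <- solve_multilabel(tr, rc$U, rc$edges, K = 2)
    expect_equal(brute_energy(tr, sol$y, rc$U, rc$edges),
                 brute_energy(tr, y_exact, rc$U, rc$edges),
                 tolerance = 1e-9)
  }
})

test_that("the expansion energy trace is strictly decreasing", {
  for (seed in 1:8) {
    tr <- random_tree(sample(4:10, 1), seed = seed + 400)
    rc <- random_costs(tr, 4, seed = seed + 500)
    sol <- solve_multilabel(tr, rc$U, rc$edges, K = 4)
    expect_true(all(diff(sol$energy) < 0))
    expect_true(validate_labeling(tr, sol$y))
    # solution is at least a strong local optimum: no single further
    # expansion move improves it
    e_final <- sol$energy[length(sol$energy)]
    again <- solve_multilabel(tr, rc$U, rc$edges, K = 4)
    expect_equal(again$energy[length(again$energy)], e_final)
  }
})

test_that("near-ties between labels do not break the solver", {
  tr <- random_tree(5, seed = 900)
  U <- matrix(1, tr$n_nodes, 2)     # exact ties everywhere
  y <- solve_binary_pylon(tr, U)
  expect_true(validate_labeling(tr, y))
  expect_equal(brute_energy(tr, y, U,
                            data.frame(i = integer(0), j = integer(0),
                                       w = numeric(0))), 1)
})
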