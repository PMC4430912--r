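# Boundary-agreement metrics, each checked against a scalar oracle or an
# analytic case.

disk_mask <- function(H, cy, cx, r) {
  outer(seq_len(H), seq_len(H), function(rr, cc) (rr - cy)^2 + (cc - cx)^2 <= r^2)
}

test_that("boundary tracing returns the closed outer contour", {
  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  b <- extract_boundary(m)
  # the 3x3 block has 8 perimeter pixels
  expect_equal(nrow(b), 8L)
  expect_setequal(paste(b[, 1], b[, 2]),
                  paste(c(2, 3, 4, 2, 4, 2, 3, 4), c(2, 2, 2, 3, 3, 4, 4, 4)))
  # closed: consecutive points (and last-to-first) are 8-adjacent
  nxt <- rbind(b[-1, , drop = FALSE], b[1, , drop = FALSE])
  expect_true(all(pmax(abs(nxt[, 1] - b[, 1]), abs(nxt[, 2] - b[, 2])) == 1))
  # a hole does not affect the outer contour
  m2 <- matrix(FALSE, 8, 8); m2[2:6, 2:6] <- TRUE
  m3 <- m2; m3[4, 4] <- FALSE
  expect_equal(extract_boundary(m3), extract_boundary(m2))
  expect_error(extract_boundary(matrix(FALSE, 4, 4)), "empty")
  single <- matrix(FALSE, 4, 4); single[2, 2] <- TRUE
  expect_error(extract_boundary(single), "single pixel")
})

test_that("average distance matches hand-computed cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(average_distance(sq, sq), 0)
  # unit squares offset by 2 in x: every vertex is 1 or 2 from the other
  # square's nearest vertex, mean 1.5, symmetric in both directions
  sq2 <- sq; sq2[, 1] <- sq2[, 1] + 2
  expect_equal(average_distance(sq, sq2), 1.5)
  expect_equal(average_distance(sq2, sq), 1.5)
  # translation by 10 in x: nearest vertices at distances 9 and 10
  sq3 <- sq; sq3[, 1] <- sq3[, 1] + 10
  expect_equal(average_distance(sq, sq3), 9.5)
  # asymmetric sets: one-point set vs two points at distances 1 and 3
  X <- rbind(c(0, 0))
  Y <- rbind(c(1, 0), c(3, 0))
  expect_equal(average_distance(X, Y), (1 + (1 + 3) / 2) / 2)
  expect_error(average_distance(matrix(0, 0, 2), Y), "non-empty")
})

test_that("the Williams index matches a scalar oracle in both forms", {
  pt <- function(x) matrix(c(x, 0), 1, 2)
  comp <- pt(0)
  obs <- list(pt(1), pt(2), pt(4))
  # distances are plain point gaps: c->o = 1, 2, 4; o-o = 1, 3, 2
  num <- mean(1 / c(1, 2, 4))
  den_std <- mean(1 / c(1, 3, 2))
  expect_equal(williams_index(comp, obs), num / den_std)
  n <- 3
  den_pr <- 2 / (n * (n - 2)) * 2 * sum(1 / c(1, 3, 2))
  expect_equal(williams_index(comp, obs, "printed"), num / den_pr)
  # the two forms differ by the fixed factor (n - 2) / (2 (n - 1))
  expect_equal(williams_index(comp, obs, "printed"),
               williams_index(comp, obs) * (n - 2) / (2 * (n - 1)))
  # computer coinciding with an observer: infinite agreement
  expect_equal(williams_index(pt(1), obs), Inf)
  # identical observers are degenerate
  expect_error(williams_index(comp, list(pt(1), pt(1), pt(2))), "degenerate")
  expect_error(williams_index(comp, obs[1:2]), "3 observers")
})

test_that("the Williams index is invariant to observer order", {
  set.seed(11)
  obs <- lapply(1:4, function(i) matrix(runif(12, 0, 10), 6, 2))
  comp <- matrix(runif(12, 0, 10), 6, 2)
  w1 <- williams_index(comp, obs)
  w2 <- williams_index(comp, obs[c(3, 1, 4, 2)])
  expect_equal(w1, w2)
})

test_that("the percentage statistic counts hits against the observer spread", {
  pt <- function(x) matrix(c(x, 0), 1, 2)
  # observers at 0, 1, 10; computer at 0.5
  # ref 1: d_c = 0.5 <= max(1, 10); ref 2: 0.5 <= max(1, 9);
  # ref 3: 9.5 <= max(10, 9) -- all three hit
  ds <- list(computer = pt(0.5), observers = list(pt(0), pt(1), pt(10)))
  expect_equal(percentage_statistic(ds), 100)
  # computer far away misses every reference
  ds_far <- list(computer = pt(1000), observers = list(pt(0), pt(1), pt(2)))
  expect_equal(percentage_statistic(ds_far), 0)
  # multi-nodule aggregation: 3 + 0 hits out of 6
  expect_equal(percentage_statistic(list(ds, ds_far)), 50)
  # partial case: computer at 4 with observers 0, 1, 2
  # ref 1: 4 <= max(1, 2) FALSE; ref 2: 3 <= max(1, 1) FALSE;
  # ref 3: 2 <= max(2, 1) TRUE -> 1/3
  ds_mid <- list(computer = pt(4), observers = list(pt(0), pt(1), pt(2)))
  expect_equal(percentage_statistic(ds_mid), 100 / 3)
  expect_error(percentage_statistic(list(computer = pt(0),
                                         observers = list(pt(1)))),
               "2 observers")
})

test_that("overlapping and difference ratios partition the union", {
  A <- matrix(FALSE, 6, 6); A[2:4, 2:4] <- TRUE          # 9 px
  B <- matrix(FALSE, 6, 6); B[3:5, 3:5] <- TRUE          # 9 px, overlap 4
  od <- overlap_difference(A, B)
  expect_equal(unname(od["OR"]), 4 / 14)
  expect_equal(unname(od["DR"]), 10 / 14)
  expect_equal(overlap_difference(A, A), c(OR = 1, DR = 0))
  C <- matrix(FALSE, 6, 6); C[1, 1] <- TRUE
  expect_equal(overlap_difference(A, C), c(OR = 0, DR = 1))
  expect_error(overlap_difference(A, matrix(FALSE, 6, 6)), "non-empty")
  # OR + DR = 1 on random region pairs
  set.seed(4)
  for (rep in 1:50) {
    a <- sample(100, sample(30, 1))
    b <- sample(100, sample(30, 1))
    expect_equal(sum(overlap_difference(a, b)), 1)
  }
})

test_that("the mean manual region is the majority vote", {
  m1 <- matrix(FALSE, 4, 4); m1[1:2, ] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[2:3, ] <- TRUE
  m3 <- matrix(FALSE, 4, 4); m3[3:4, ] <- TRUE
  mv <- mean_manual_region(list(m1, m2, m3))
  expect_equal(mv, m1 & m2 | m2 & m3 | m1 & m3)   # rows 2 and 3
  expect_equal(unname(rowSums(mv)), c(0, 4, 4, 0))
  # with 4 observers the threshold is ceiling(4/2) = 2 votes
  mv4 <- mean_manual_region(list(m1, m1, m2, m3))
  expect_true(all(mv4[1, ]))
  expect_error(mean_manual_region(list()), "at least one")
})

test_that("curve rasterization matches the analytic square and nests on disks", {
  sq <- rbind(c(1.5, 1.5), c(5.5, 1.5), c(5.5, 5.5), c(1.5, 5.5))
  m <- curve_to_mask(sq, c(8, 8))
  expect_equal(sum(m), 16L)
  expect_true(all(m[2:5, 2:5]))
  expect_false(any(m[c(1, 6:8), ]) || any(m[, c(1, 6:8)]))
  # tracing a disk and rasterizing its contour recovers a region nested
  # between the disk interior and the full disk
  d <- disk_mask(21, 11, 11, 6)
  b <- extract_boundary(d)
  rec <- curve_to_mask(b, c(21, 21))
  expect_true(all(!rec | d))                       # subset of the disk
  on_contour <- matrix(FALSE, 21, 21)
  on_contour[cbind(b[, 2], b[, 1])] <- TRUE
  expect_true(all(!(d & !on_contour) | rec))       # contains the interior
})

test_that("the full report behaves at the identical-delineation extreme", {
  d <- disk_mask(31, 16, 16, 9)
  rep1 <- evaluate_boundaries(d, list(d, d, d))
  # observers identical to each other: the Williams index degrades to NA
  expect_true(is.na(rep1$williams_index))
  expect_equal(rep1$percentage_statistic, 100)
  expect_equal(rep1$overlapping_ratio, 1)
  expect_equal(rep1$difference_ratio, 0)
  expect_equal(rep1$ad_computer, c(0, 0, 0))
  # distinct observers around the truth: index near 1, OR high
  obs <- list(disk_mask(31, 16, 16, 8), disk_mask(31, 16, 16, 9),
              disk_mask(31, 17, 16, 9), disk_mask(31, 16, 17, 8))
  rep2 <- evaluate_boundaries(d, obs)
  expect_true(is.finite(rep2$williams_index) || is.infinite(rep2$williams_index))
  expect_gt(rep2$overlapping_ratio, 0.8)
  expect_equal(rep2$overlapping_ratio + rep2$difference_ratio, 1)
  expect_output(print(rep2), "Williams index")
})
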