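# two-block fixture: left half weights = a, right half = b
two_block_grid <- function(M = 10, N = 10, a = c(0, 0, 0), b = c(4, 0, 0)) {
  lab <- rep(rep(c(1, 2), c(N / 2, N / 2)), times = M)
  W <- matrix(0, M * N, length(a))
  W[lab == 1, ] <- matrix(a, sum(lab == 1), length(a), byrow = TRUE)
  W[lab == 2, ] <- matrix(b, sum(lab == 2), length(b), byrow = TRUE)
  fixture_grid(W, M, N)
}

test_that("U-matrix: constant map is all zero, block boundary localizes, translation invariant", {
  g <- fixture_grid(matrix(3.7, 12, 5), 3, 4)
  expect_equal(compute_umatrix(g), matrix(0, 3, 4))

  g2 <- two_block_grid()
  um <- compute_umatrix(g2)
  # nonzero exactly on the two columns adjacent to the boundary
  expect_true(all(um[, c(5, 6)] > 0))
  expect_equal(um[, c(1:4, 7:10)], matrix(0, 10, 8), ignore_attr = TRUE)

  g3 <- g2
  g3$weights <- g3$weights + matrix(c(10, -3, 0.5), nrow(g3$weights), 3,
                                    byrow = TRUE)
  expect_equal(compute_umatrix(g3), um, tolerance = 1e-12)
})

test_that("watershed recovers trivial and block structure and always partitions", {
  expect_equal(watershed_basins(matrix(0, 6, 6)), matrix(1L, 6, 6))

  um <- compute_umatrix(two_block_grid())
  lab <- watershed_basins(um)
  expect_identical(max(lab), 2L)
  # the two plateaus away from the boundary get consistent labels
  expect_true(all(lab[, 1:4] == lab[1, 1]))
  expect_true(all(lab[, 7:10] == lab[1, 10]))
  expect_false(lab[1, 1] == lab[1, 10])

  set.seed(61)
  for (i in 1:10) {
    u <- matrix(stats::runif(64), 8, 8)
    u <- (u - min(u)) / (max(u) - min(u))
    lb <- watershed_basins(u)
    expect_true(all(lb >= 1))
    expect_setequal(unique(as.integer(lb)), seq_len(max(lb)))
    expect_true(regions_connected(lb))
  }
})

# U-matrix fixture with two deep basins and one shallow satellite dip.
# Column profile (constant down rows): deep valley at cols 1-2 (u = 0),
# ridge 1.0 at col 4, deep valley at cols 6-7 (u = 0.05), shallow dip at
# col 9 (u = 0.55) behind a rim of 0.65.
satellite_umatrix <- function() {
  prof <- c(0, 0, 0.5, 1, 0.5, 0.05, 0.05, 0.65, 0.55, 0.65)
  matrix(prof, nrow = 6, ncol = 10, byrow = TRUE)
}

test_that("shallow-basin merging follows the saddle-depth rule", {
  u <- satellite_umatrix()
  lab <- watershed_basins(u)
  expect_identical(max(lab), 3L)

  # depth_frac 0: unchanged
  expect_identical(merge_shallow_basins(lab, u, 0), lab)

  # default 0.15: satellite (depth 0.65 - 0.55 = 0.10) absorbed into its
  # saddle neighbor; the two deep basins (depths 1-0 and 0.65-0.05) survive
  m <- merge_shallow_basins(lab, u, 0.15)
  expect_identical(max(m), 2L)
  expect_true(all(m[, 8:10] == m[1, 7]))   # satellite joined the second basin
  expect_false(m[1, 1] == m[1, 7])

  # depth_frac 1: single basin
  expect_identical(max(merge_shallow_basins(lab, u, 1)), 1L)

  # monotonicity: B non-increasing in depth_frac
  set.seed(62)
  for (i in 1:5) {
    u2 <- matrix(stats::runif(100), 10, 10)
    u2 <- (u2 - min(u2)) / (max(u2) - min(u2))
    l2 <- watershed_basins(u2)
    Bs <- vapply(c(0, 0.1, 0.25, 0.5, 1),
                 function(df) max(merge_shallow_basins(l2, u2, df)), numeric(1))
    expect_true(all(diff(Bs) <= 0))
    expect_true(regions_connected(merge_shallow_basins(l2, u2, 0.25)))
  }
})

test_that("build_posture_map picks representatives consistent with their basins", {
  set.seed(63)
  centers <- matrix(stats::rnorm(5 * 8, sd = 6), 5)
  X <- centers[sample(5, 800, TRUE), ] + matrix(stats::rnorm(800 * 8, sd = 0.3), 800)
  g <- som_train(X, 8, 8, som_schedule(n_epochs = 40, seed = 5))
  pm <- build_posture_map(g, X, depth_frac = 0.15)
  expect_gte(pm$n_units, 1L)
  expect_lte(pm$n_units, 64L)
  # merging never increases the count
  raw <- watershed_basins(pm$umatrix)
  expect_lte(pm$n_units, max(raw))
  # each representative's winner lies in its own basin
  for (b in seq_len(pm$n_units)) {
    expect_identical(assign_basin(pm, pm$representatives[b, ]), b)
  }
  expect_error(build_posture_map(g, X[, 1:3]), "dimension")
})

test_that("assign_basin matches the brute-force winner lookup", {
  set.seed(64)
  g <- fixture_grid(matrix(stats::rnorm(100 * 3), 100), 10, 10)
  um <- compute_umatrix(g)
  lab <- merge_shallow_basins(watershed_basins(um), um, 0.1)
  pm <- build_posture_map(g, depth_frac = 0.1)
  X <- matrix(stats::rnorm(500 * 3), ncol = 3)
  brute <- apply(X, 1, function(x) {
    j <- which.min(colSums((t(g$weights) - x)^2))
    as.integer(t(pm$labeling))[j]
  })
  expect_identical(assign_basins(pm, X), as.integer(brute))
  # a copy of any neuron's weight maps to that neuron's basin
  for (j in c(1, 42, 100)) {
    expect_identical(assign_basin(pm, g$weights[j, ]),
                     as.integer(t(pm$labeling))[j])
  }
})
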