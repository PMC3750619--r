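test_that("hand-enumerated depths are reproduced", {
  # three distinct 1-d points: middle lies in all 3 bands, extremes in 2
  expect_equal(mbd(matrix(1:3, ncol = 1))$depth, c(2/3, 1, 2/3))
  # two samples: each coordinate is an endpoint of the only band
  expect_equal(mbd(matrix(rnorm(2 * 7), nrow = 2))$depth, c(1, 1))
  # identical rows: every band degenerates to the common point
  expect_equal(mbd(matrix(1, 5, 3))$depth, rep(1, 5))
  # tied values: rows 1-2 have minimal rank 1 with multiplicity 2
  expect_equal(mbd(matrix(c(1, 1, 2), ncol = 1))$depth, c(1, 1, 2/3))
})

test_that("fast multiplicity counting matches the pairwise oracle", {
  set.seed(101)
  for (rep in 1:30) {
    x <- random_matrix(sample(3:30, 1), sample(1:100, 1),
                       ties = rep %% 2 == 0)
    expect_lt(max(abs(mbd(x)$depth - mbd(x, method = "pairwise")$depth)),
              1e-12)
  }
})

test_that("reference-set depth agrees with the oracle and the formula", {
  # l1 = 1, l2 = 2, eta = 1: the new point sits inside all 3 bands
  expect_equal(mbd(matrix(2), xref = matrix(1:3, ncol = 1))$depth, 1)
  set.seed(7)
  xref <- random_matrix(12, 9, ties = TRUE)
  xnew <- random_matrix(5, 9)
  expect_equal(mbd(xnew, xref = xref)$depth,
               mbd(xnew, xref = xref, method = "pairwise")$depth,
               tolerance = 1e-13)
  # points beyond the coordinate-wise range of the reference have depth 0
  above <- matrix(apply(xref, 2, max) + 1, nrow = 1)
  below <- matrix(apply(xref, 2, min) - 1, nrow = 1)
  expect_identical(mbd(above, xref = xref)$depth, 0)
  expect_identical(mbd(below, xref = xref)$depth, 0)
})

test_that("a reference row receives exactly its in-sample depth", {
  set.seed(11)
  for (rep in 1:10) {
    x <- random_matrix(sample(3:20, 1), sample(2:40, 1), ties = TRUE)
    expect_equal(mbd(x, xref = x)$depth, mbd(x)$depth, tolerance = 1e-14)
  }
})

test_that("depth is invariant under strictly increasing column transforms", {
  set.seed(5)
  x <- random_matrix(15, 25, ties = TRUE)
  expect_equal(mbd(x^3)$depth, mbd(x)$depth)
  expect_equal(mbd(exp(x))$depth, mbd(x)$depth)
  mixed <- x
  mixed[, 1:10] <- atan(mixed[, 1:10])       # different map per block
  mixed[, 11:25] <- 2 * mixed[, 11:25] + 7
  expect_equal(mbd(mixed)$depth, mbd(x)$depth)
})

test_that("depth respects row permutation and the [2/n, 1] bounds", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    x <- random_matrix(n, sample(1:30, 1), ties = TRUE)
    perm <- sample(n)
    expect_equal(mbd(x[perm, ])$depth, mbd(x)$depth[perm])
    dp <- mbd(x)$depth
    expect_true(all(dp >= 2 / n - 1e-15) && all(dp <= 1 + 1e-15))
  }
})

test_that("ordering is deepest-first with stable index tie-break", {
  expect_identical(depth_ordering(c(0.5, 0.9, 0.7)), c(2L, 3L, 1L))
  expect_identical(depth_ordering(c(0.8, 0.8)), c(1L, 2L))
  expect_identical(mbd(matrix(rnorm(2 * 4), 2))$ordering, c(1L, 2L))
  dp <- mbd(random_matrix(12, 8))
  expect_true(all(diff(dp$depth[dp$ordering]) <= 0))
  expect_setequal(dp$ordering, 1:12)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(mbd(matrix(1, 1, 3)), "insufficient samples")
  expect_error(mbd(matrix(c(1, NA, 3, 4), 2)), "invalid matrix")
  expect_error(mbd(matrix(c(1, Inf, 3, 4), 2)), "invalid matrix")
  expect_error(mbd(matrix(1:4, 2), xref = matrix(1:9, 3)),
               "dimension mismatch")
  expect_error(mbd(matrix(1:4, 2), xref = matrix(1:3, 1)),
               "insufficient reference")
  expect_error(depth_ordering(numeric(0)), "no samples")
})

test_that("fast MBD scales to large matrices", {
  set.seed(3)
  x <- matrix(rnorm(200 * 1000), 200)
  expect_lt(system.time(mbd(x))["elapsed"], 5)
})
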