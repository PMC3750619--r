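test_that("trimmed mean honours the retention contract", {
  set.seed(21)
  x <- random_matrix(25, 12)
  # nothing trimmed: ordinary column mean, all rows retained
  t0 <- tmean(x, alpha = 0)
  expect_identical(t0$retained, 1:25)
  expect_equal(t0$tm, colMeans(x))
  # ceil((1 - 0.25) * 25) = 19 deepest rows retained
  t25 <- tmean(x, alpha = 0.25)
  expect_length(t25$retained, 19)
  expect_setequal(t25$retained, mbd(x)$ordering[1:19])
  for (a in c(0.1, 0.4, 0.8))
    expect_length(tmean(x, alpha = a)$retained, ceiling((1 - a) * 25))
  # identical rows: the trimmed mean is the common row at every alpha
  y <- matrix(rep(c(3, -1, 2), each = 6), nrow = 6)
  for (a in c(0, 0.3, 0.6))
    expect_equal(unname(tmean(y, alpha = a)$tm), c(3, -1, 2))
  expect_error(tmean(x, alpha = 1), "invalid trimming proportion")
  expect_error(tmean(x, alpha = -0.1), "invalid trimming proportion")
})

test_that("trimmed mean resists gross contamination", {
  set.seed(33)
  x <- contaminated_matrix(n_clean = 20, n_out = 2, d = 30, magnitude = 50)
  truth <- rep(0, 30)                    # clean-population mean
  err_trim <- sqrt(sum((tmean(x, alpha = 0.2)$tm - truth)^2))
  err_mean <- sqrt(sum((colMeans(x) - truth)^2))
  expect_lt(err_trim, err_mean)
  # the displaced rows are the first to be trimmed out
  expect_false(any(21:22 %in% tmean(x, alpha = 0.2)$retained))
})

test_that("central bands cover the right samples and nest", {
  set.seed(44)
  x <- random_matrix(25, 15)
  dp <- mbd(x)
  # minimal central set: the band collapses onto the deepest sample
  b1 <- central_band(x, 1 / 25)
  expect_equal(b1$lower, b1$upper)
  expect_equal(unname(b1$lower), unname(x[dp$ordering[1], ]))
  # p = 1: the whole-data envelope
  ball <- central_band(x, 1)
  expect_equal(unname(ball$lower), apply(x, 2, min))
  expect_equal(unname(ball$upper), apply(x, 2, max))
  # 25% of 25 samples: the 7 most central ones
  expect_length(central_band(x, 0.25)$samples, 7)
  # nesting across a partition
  part <- central_partition(x, c(0.25, 0.5, 0.75, 1))
  expect_length(part, 4)
  for (j in 1:3) {
    expect_true(all(part[[j]]$lower >= part[[j + 1]]$lower))
    expect_true(all(part[[j]]$upper <= part[[j + 1]]$upper))
    expect_true(all(part[[j]]$samples %in% part[[j + 1]]$samples))
  }
  expect_error(central_band(x, 0), "invalid proportion")
  expect_error(central_band(x, 1.2), "invalid proportion")
  expect_error(central_partition(x, c(0.5, 0.5)), "invalid band limits")
  expect_error(central_partition(x, c(0.8, 0.2)), "invalid band limits")
})

test_that("scale curve is monotone and equivariant", {
  set.seed(55)
  for (rep in 1:10) {
    x <- random_matrix(sample(5:25, 1), sample(2:30, 1))
    sc <- scale_curve(x)
    expect_equal(sc$p, seq_len(nrow(x)) / nrow(x))
    expect_true(all(diff(sc$area) >= -1e-12))
    expect_equal(sc$area[1], 0)          # single central sample
    # translation leaves areas unchanged; scaling by c multiplies them
    shiftv <- rnorm(ncol(x))
    expect_equal(scale_curve(x + matrix(shiftv, nrow(x), ncol(x),
                                        byrow = TRUE))$area, sc$area)
    expect_equal(scale_curve(3 * x)$area, 3 * sc$area)
  }
})

test_that("degenerate scale curves are zero", {
  x1 <- matrix(rnorm(10), ncol = 1)      # d = 1: zero-width domain
  expect_true(all(scale_curve(x1)$area == 0))
  xc <- matrix(2, 6, 8)                  # all rows identical
  expect_true(all(scale_curve(xc)$area == 0))
})

test_that("a 3x-inflated group dominates the scale curve everywhere", {
  set.seed(66)
  x <- random_matrix(25, 20)
  center <- colMeans(x)
  y <- sweep(sweep(x, 2, center) * 3, 2, center, `+`)
  sx <- scale_curve(x)$area
  sy <- scale_curve(y)$area
  expect_true(all(sy[-1] > sx[-1]))      # p = 1/n is degenerate (both 0)
})
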