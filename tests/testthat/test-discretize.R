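test_that("equal-width binning maps the ROI range onto 1..n_bins", {
  a <- array(NA_real_, c(32, 1, 1))
  a[, 1, 1] <- 0:31
  m <- array(TRUE, c(32, 1, 1))
  d <- discretize(a, m, n_bins = 32)
  expect_equal(as.vector(d$levels[, 1, 1]), 1:32)
  expect_equal(d$n_levels, 32L)

  # max intensity lands in the top bin, not a phantom bin n+1
  expect_equal(max(d$levels, na.rm = TRUE), 32L)
})

test_that("constant ROI collapses to a single level", {
  a <- array(5, c(3, 3, 3)); m <- array(TRUE, c(3, 3, 3))
  d <- discretize(a, m)
  expect_equal(d$n_levels, 1L)
  expect_true(all(d$levels == 1L))
})

test_that("out-of-mask voxels carry the NA sentinel; empty mask errors", {
  a <- array(rnorm(27), c(3, 3, 3))
  m <- array(FALSE, c(3, 3, 3)); m[1:2, 1, 1] <- TRUE
  d <- discretize(a, m, n_bins = 4)
  expect_true(all(is.na(d$levels[!m])))
  expect_true(all(!is.na(d$levels[m])))
  expect_error(discretize(a, array(FALSE, c(3, 3, 3))), "empty ROI")
  expect_error(discretize(a, m, n_bins = 1), "n_bins")
})

test_that("uniform-random intensities fill bins near-uniformly (multinomial bound)", {
  set.seed(11)
  n <- 40000; bins <- 16
  a <- array(runif(n), c(n, 1, 1))
  m <- array(TRUE, c(n, 1, 1))
  d <- discretize(a, m, n_bins = bins)
  occ <- tabulate(d$levels[m], nbins = bins)
  expected <- n / bins
  sigma <- sqrt(n * (1 / bins) * (1 - 1 / bins))
  expect_true(all(abs(occ - expected) < 4 * sigma))
})

test_that("intensity shift leaves discretized levels identical", {
  set.seed(3)
  a <- array(rnorm(125, 50, 10), c(5, 5, 5))
  m <- array(runif(125) < 0.7, c(5, 5, 5)); m[1, 1, 1] <- TRUE
  d1 <- discretize(a, m)
  d2 <- discretize(a + 123.4, m)
  expect_identical(d1$levels, d2$levels)
})

test_that("first-order statistics match hand arithmetic and handle constants", {
  a <- array(c(1, 2, 3, 4), c(4, 1, 1)); m <- array(TRUE, c(4, 1, 1))
  f <- first_order_features(a, m)
  expect_equal(unname(f["Stats_mean"]), 2.5)
  expect_equal(unname(f["Stats_var"]), 1.25)   # population variance
  expect_equal(unname(f["Stats_rms"]), sqrt(7.5))

  cst <- first_order_features(array(7, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  expect_equal(unname(cst["Stats_mean"]), 7)
  expect_equal(unname(cst["Stats_rms"]), 7)
  expect_equal(unname(cst[c("Stats_std", "Stats_var", "Stats_iqr")]), c(0, 0, 0))
  expect_equal(unname(cst[c("Stats_p10", "Stats_p90")]), c(7, 7))
})

test_that("std of large standard-normal sample is near 1 (sampling oracle)", {
  set.seed(5)
  n <- 1e5
  a <- array(rnorm(n), c(n, 1, 1))
  f <- first_order_features(a, array(TRUE, c(n, 1, 1)))
  expect_lt(abs(f[["Stats_std"]] - 1), 0.02)
  # p10/p90 near the normal quantiles
  expect_lt(abs(f[["Stats_p10"]] - qnorm(0.1)), 0.03)
  expect_lt(abs(f[["Stats_p90"]] - qnorm(0.9)), 0.03)
})

test_that("first-order features are invariant to voxel reordering", {
  set.seed(9)
  vals <- rnorm(60)
  a1 <- array(vals, c(60, 1, 1))
  a2 <- array(sample(vals), c(60, 1, 1))
  m <- array(TRUE, c(60, 1, 1))
  expect_equal(first_order_features(a1, m), first_order_features(a2, m))
})
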