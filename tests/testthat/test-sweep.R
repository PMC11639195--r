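test_that("published grid ranges are reproduced", {
  g <- defaultGrid("tvl1")
  expect_equal(range(g@axes$lambda), c(0.01, 3.5), tolerance = 1e-9)
  expect_gte(length(g@axes$lambda), 15L)

  g <- defaultGrid("nlm")
  expect_lte(max(g@axes$sigma), 7000)
  expect_gt(min(g@axes$sigma), 0)  # zero endpoint replaced

  g <- defaultGrid("bm3d")
  expect_lte(max(g@axes$noiseSigma), 10000)
  expect_gt(min(g@axes$noiseSigma), 0)

  g <- defaultGrid("atm")
  expect_true(all(g@axes$lambda >= 2 & g@axes$lambda <= 14))

  # bilateral: range axis spans [100 v, 11000 v]
  g <- defaultGrid("bilateral", backgroundVariance = 400)
  expect_equal(range(g@axes$sigmaR2), c(4e4, 4.4e6), tolerance = 1e-9)
  expect_error(defaultGrid("bilateral"), "backgroundVariance")
  expect_error(defaultGrid("sharpen"), "unknown")
})

test_that("sweep returns the argmax with a consistent percent increase", {
  set.seed(40)
  truth <- cherenkovImage(matrix(800, 48, 48))
  noisy <- cherenkovImage(pmax(pixels(truth) + rnorm(48^2, 0, 60), 0))
  grid <- new("SweepGrid", filterId = "atm",
              axes = list(lambda = c(2, 4, 8)), fixed = list(beta = 7L))
  r1 <- suppressWarnings(sweepFilter(truth, noisy, grid))
  expect_identical(nrow(r1@trace), 3L)
  expect_true(all(r1@bestPsnr >= r1@trace$psnr, na.rm = TRUE))
  expect_equal(r1@percentIncrease,
               100 * (r1@bestPsnr - r1@noisyPsnr) / r1@noisyPsnr,
               tolerance = 1e-10)
  # end-to-end determinism
  r2 <- suppressWarnings(sweepFilter(truth, noisy, grid))
  expect_identical(r1@trace, r2@trace)
  expect_identical(r1@bestPsnr, r2@bestPsnr)

  # single-point grid: that point is the argmax
  g1 <- new("SweepGrid", filterId = "tvl1",
            axes = list(lambda = 0.5), fixed = list(nIter = 20L))
  rs <- sweepFilter(truth, noisy, g1)
  expect_equal(rs@bestParams@lambda, 0.5)
})

test_that("exact PSNR ties break toward the least aggressive parameter", {
  cst <- cherenkovImage(matrix(5, 24, 24))
  grid <- new("SweepGrid", filterId = "tvl1",
              axes = list(lambda = c(0.2, 1.5)), fixed = list(nIter = 10L))
  # a constant image is a fixed point at any lambda: every PSNR is +Inf,
  # the largest (least smoothing) lambda must win
  r <- suppressWarnings(sweepFilter(cst, cst, grid))
  expect_equal(r@bestParams@lambda, 1.5)
})

test_that("a boundary argmax raises a warning", {
  set.seed(41)
  truth <- cherenkovImage(matrix(1000, 40, 40))
  noisy <- cherenkovImage(pmax(pixels(truth) + rnorm(1600, 0, 80), 0))
  grid <- new("SweepGrid", filterId = "nlm",
              axes = list(sigma = c(20, 800)),
              fixed = list(window = 8L, patch = 4L))
  expect_warning(sweepFilter(truth, noisy, grid), "boundary")
})

test_that("an all-failing grid is fatal", {
  tiny <- cherenkovImage(matrix(1, 16, 16))
  grid <- new("SweepGrid", filterId = "bm3d",
              axes = list(noiseSigma = c(10, 50)), fixed = list())
  expect_error(suppressWarnings(sweepFilter(tiny, tiny, grid)),
               "every grid point failed")
})
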