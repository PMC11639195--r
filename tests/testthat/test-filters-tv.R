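test_that("TV-L1 limit identities hold", {
  cst <- cherenkovImage(matrix(42, 20, 20))
  expect_equal(pixels(denoise(cst, tvParams(0.7))), pixels(cst),
               tolerance = 1e-12)

  set.seed(4)
  img <- cherenkovImage(matrix(runif(400, 0, 1000), 20))
  # fidelity-dominated limit: enormous lambda recreates the input
  out <- pixels(denoise(img, tvParams(1e6)))
  expect_lt(max(abs(out - pixels(img))) / diff(range(pixels(img))), 1e-3)
  # zero iterations: identity contract
  expect_identical(pixels(denoise(img, tvParams(0.3, nIter = 0L))),
                   pixels(img))
})

test_that("TV-L1 cost is non-increasing and smooths an impulse", {
  spike <- matrix(0, 9, 9); spike[5, 5] <- 100
  img <- cherenkovImage(spike)
  out <- denoise(img, tvParams(0.1))
  tr <- imageMetadata(out)$tvCostTrace
  expect_true(all(diff(tr) <= 1e-12 * tr[1]))
  expect_lt(pixels(out)[5, 5], 100)
  # cost of the output does not exceed the input's
  expect_lte(tail(tr, 1), tr[1])
})

test_that("TV-L1 approaches the brute-force minimum on a tiny instance", {
  # 3x3 instance, exhaustive search over a coarse 3-level intensity grid
  g <- matrix(0, 3, 3); g[2, 2] <- 100
  lam <- 0.1
  cost_of <- function(x, gg) {
    gx <- cbind(x[, 2:3] - x[, 1:2], c(0, 0, 0))
    gy <- rbind(x[2:3, ] - x[1:2, ], c(0, 0, 0))
    sum(sqrt(gx^2 + gy^2)) + lam * sum(abs(x - gg))
  }
  levels <- c(0, 50, 100)
  gridBest <- Inf
  idx <- rep(1L, 9L)
  for (n in seq_len(3^9)) {
    x <- matrix(levels[idx], 3, 3)
    gridBest <- min(gridBest, cost_of(x, g))
    # odometer increment
    d <- 1L
    while (d <= 9L) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= 3L) break
      idx[d] <- 1L; d <- d + 1L
    }
  }
  out <- denoise(cherenkovImage(g), tvParams(lam, nIter = 2000L))
  # the continuous minimum is below any grid point; the iterate must at
  # least match the exhaustive grid optimum
  expect_lte(cost_of(pixels(out), g), gridBest + 1e-6)
})

test_that("TV-L1 preserves shape and pitch and rejects bad parameters", {
  img <- cherenkovImage(matrix(runif(48), 6, 8), pixelPitch = c(0.3, 0.4))
  out <- denoise(img, tvParams(0.5, nIter = 10L))
  expect_identical(dim(pixels(out)), c(6L, 8L))
  expect_identical(pixelPitch(out), c(0.3, 0.4))
  expect_error(tvParams(-1), "lambda")
  expect_error(tvParams(Inf), "lambda")
})
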