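test_that("trimmed mean endpoints and hand-worked case", {
  expect_identical(trimmedMean(1:9, 0), 5)          # plain average
  expect_identical(trimmedMean(1:9, 0.5), 5L)       # median filter limit
  expect_identical(trimmedMean(c(9:5, 1:4), 0.5), 5L)
  # ceil(0.12 * 9) = 2 trimmed per end -> mean(3..7) = 5
  expect_identical(trimmedMean(c(1:8, 100), 0.12), 5)
  expect_error(trimmedMean(1:9, 0.6))
  expect_error(trimmedMean(1:9, -0.1))
})

test_that("adaptive filter equals the literal per-pixel re-evaluation", {
  # two-level image: plateau 1000 with one bright speck
  m <- matrix(1000, 21, 21)
  m[8, 13] <- 4000
  out <- pixels(denoise(cherenkovImage(m), atmParams(2, beta = 31L,
                                                     delta = 5)))
  expect_equal(out, atm_oracle(m, 31L, 2, 5), tolerance = 1e-12)

  # a second configuration exercises different window sizes
  set.seed(14)
  m2 <- matrix(runif(15 * 15, 0, 2000), 15)
  out2 <- pixels(denoise(cherenkovImage(m2), atmParams(3, beta = 9L,
                                                       delta = 5)))
  expect_equal(out2, atm_oracle(m2, 9L, 3, 5), tolerance = 1e-12)
})

test_that("low signal gets the maximum window and the brightest pixel a median", {
  # pixel below delta -> window beta: a dark pixel inside a bright field
  # averages the full beta-window
  m <- matrix(600, 9, 9)
  m[5, 5] <- 3
  out <- pixels(denoise(cherenkovImage(m), atmParams(2, beta = 5L,
                                                     delta = 5)))
  # oracle confirms the beta-window trimmed mean at the dark pixel
  expect_equal(out[5, 5], atm_oracle(m, 5L, 2, 5)[5, 5], tolerance = 1e-12)
  # x = Max, lambda = 2 -> alpha = 0.5 -> median filtering at the peak
  m3 <- matrix(100, 7, 7)
  m3[4, 4] <- 5000
  out3 <- pixels(denoise(cherenkovImage(m3), atmParams(2, beta = 7L)))
  expect_identical(out3[4, 4], 100)  # median of its window
})

test_that("all-zero images pass through and huge lambda gives a box mean", {
  z <- matrix(0, 10, 10)
  expect_identical(pixels(denoise(cherenkovImage(z), atmParams(2))), z)

  set.seed(15)
  m <- matrix(runif(144, 100, 2000), 12)
  out <- pixels(denoise(cherenkovImage(m), atmParams(1e15, beta = 5L,
                                                     delta = 0)))
  expect_equal(out, gauss_blur_oracle(m, 1e9, 5L), tolerance = 1e-9)
  expect_error(atmParams(1.5), "lambda")
  expect_error(atmParams(3, beta = 4L), "beta")
})
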