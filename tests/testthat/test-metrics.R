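test_that("PSNR hand values, sentinel and scaling identity", {
  t <- matrix(c(0, 100, 100, 0), 2)
  x <- t; x[1] <- 10
  expect_equal(psnr(t, x), 20 * log10(100 / 5), tolerance = 1e-12)
  expect_identical(psnr(t, t), Inf)
  # doubling every residual lowers PSNR by exactly 20 log10(2)
  set.seed(23)
  truth <- matrix(runif(100, 0, 500), 10)
  e <- matrix(rnorm(100, 0, 5), 10)
  expect_equal(psnr(truth, truth + e) - psnr(truth, truth + 2 * e),
               20 * log10(2), tolerance = 1e-10)
  expect_error(psnr(matrix(0, 2, 2), matrix(1, 2, 2)), "peak")
  expect_error(psnr(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes")
  # PSNR strictly decreases as independent noise grows
  ps <- vapply(c(2, 8, 32), function(s) {
    set.seed(50)
    psnr(truth, truth + matrix(rnorm(100, 0, s), 10))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("ESF extraction recovers edge angle and the analytic profile", {
  img <- blurred_edge_image(128, 96, sb = 2, angleDeg = 5)
  esf <- extractESF(img, c(1L, 1L, 96L, 128L))
  expect_lt(abs(esf@edgeAngle - 5), 0.2)
  # the ESF of a Gaussian-blurred step is the Gaussian CDF
  ref <- 1000 * pnorm(esf@positions / 2)
  expect_lt(max(abs(esf@values - ref)), 0.02 * 1000)

  flat <- cherenkovImage(matrix(500, 40, 40))
  expect_error(extractESF(flat, c(1L, 1L, 40L, 40L)), "no edge")
})

test_that("MTF matches closed forms and is scale and shift invariant", {
  img <- blurred_edge_image(128, 96, sb = 2, angleDeg = 5)
  esf <- extractESF(img, c(1L, 1L, 96L, 128L))
  mtf <- esfToMTF(esf)
  keep <- mtf@freqs <= 0.25 & mtf@freqs > 0
  ref <- exp(-2 * pi^2 * 4 * mtf@freqs[keep]^2)
  expect_lt(max(abs(mtf@values[keep] - ref)), 0.02)
  s <- mtfSummary(mtf)
  expect_equal(s$mtf50, sqrt(log(2) / (2 * pi^2 * 4)), tolerance = 0.03)
  expect_equal(s$mtf10, sqrt(log(10) / (2 * pi^2 * 4)), tolerance = 0.03)

  # intensity rescaling leaves the MTF unchanged
  img2 <- cherenkovImage(pixels(img) * 7.3)
  mtf2 <- esfToMTF(extractESF(img2, c(1L, 1L, 96L, 128L)))
  expect_equal(mtfSummary(mtf2)$mtf50, s$mtf50, tolerance = 1e-9)

  # edge shifted by 3 px: MTF50 within 1%
  img3 <- blurred_edge_image(128, 96, sb = 2, angleDeg = 5, edgeCol = 51)
  mtf3 <- esfToMTF(extractESF(img3, c(1L, 1L, 96L, 128L)))
  expect_lt(abs(mtfSummary(mtf3)$mtf50 - s$mtf50) / s$mtf50, 0.01)

  # a perfect step ESF transfers flatly through a quarter of the band
  pos <- seq(-10, 10, by = 0.25)
  stepEsf <- new("ESFCurve", positions = pos,
                 values = ifelse(pos > 0, 1000, 0), oversampling = 4,
                 edgeAngle = 5)
  mtfS <- esfToMTF(stepEsf)
  expect_true(all(mtfS@values[mtfS@freqs <= 0.25] >= 0.99))

  # monotone curve never reaching 10%: absent, not extrapolated
  flatish <- new("MTFCurve", freqs = seq(0, 0.5, length.out = 11),
                 values = seq(1, 0.4, length.out = 11))
  expect_true(is.na(mtfSummary(flatish)$mtf10))
  expect_false(is.na(mtfSummary(flatish)$mtf50))
})

test_that("10-90 rise distance follows the Gaussian closed form", {
  img <- blurred_edge_image(160, 96, sb = 2, angleDeg = 5)
  esf <- extractESF(img, c(1L, 1L, 96L, 160L))
  expect_equal(riseDistance(esf), 2 * qnorm(0.9) * 2, tolerance = 0.03)
  # linear in the blur scale
  img2 <- blurred_edge_image(160, 96, sb = 4, angleDeg = 5)
  esf2 <- extractESF(img2, c(1L, 1L, 96L, 160L))
  expect_equal(riseDistance(esf2) / riseDistance(esf), 2, tolerance = 0.03)
  # ideal step ESF: within one oversampled bin
  pos <- seq(-10, 10, by = 0.25)
  esfS <- new("ESFCurve", positions = pos,
              values = ifelse(pos > 0, 1000, 0), oversampling = 4,
              edgeAngle = 5)
  expect_lte(riseDistance(esfS), 1 / esfS@oversampling + 1e-9)
})
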