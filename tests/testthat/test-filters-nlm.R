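test_that("NLM fixed points and degenerate kernel limits", {
  cst <- cherenkovImage(matrix(3.5, 16, 16))
  p <- nlmParams(100, window = 6L, patch = 2L)
  expect_equal(pixels(denoise(cst, p)), pixels(cst), tolerance = 1e-12)
  expect_equal(pixels(nlmDenoiseBrute(cst, p)), pixels(cst),
               tolerance = 1e-12)

  # sigma -> 0+: only the self weight survives (mirror duplicates at the
  # border share the self intensity, so the identity still holds exactly)
  set.seed(9)
  img <- cherenkovImage(matrix(runif(15 * 15, 0, 1000), 15))
  tiny <- nlmParams(1e-3, window = 6L, patch = 2L)
  expect_lt(max(abs(pixels(denoise(img, tiny)) - pixels(img))), 1e-6)

  expect_error(nlmParams(0), "sigma")
  expect_error(nlmParams(-5), "sigma")
  expect_error(nlmParams(50, window = 2L, patch = 4L), "window")
})

test_that("brute-force NLM matches literal site-by-site evaluation", {
  set.seed(21)
  m <- matrix(runif(144, 0, 255), 12)
  p <- nlmParams(50, window = 6L, patch = 2L)
  b <- pixels(nlmDenoiseBrute(cherenkovImage(m), p))
  for (site in list(c(4L, 4L), c(7L, 9L), c(12L, 12L))) {
    expect_equal(b[site[1], site[2]],
                 nlm_site_oracle(m, site[1], site[2], 50, 3L, 1L),
                 tolerance = 1e-12)
  }
  # Gaussian patch-kernel variant (oracle flag) matches too
  bg <- pixels(nlmDenoiseBrute(cherenkovImage(m), p, gaussKernel = TRUE,
                               gaussSigma = 1.5))
  expect_equal(bg[7, 9],
               nlm_site_oracle(m, 7L, 9L, 50, 3L, 1L, gauss = TRUE,
                               gsigma = 1.5),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(b, bg)))
})

test_that("fast NLM equals the brute-force oracle on random images", {
  set.seed(33)
  for (r in 1:5) {
    m <- matrix(runif(24 * 24, 0, 4000), 24)
    img <- cherenkovImage(m)
    p <- nlmParams(sample(c(80, 400, 2000), 1), window = 8L, patch = 4L)
    f <- pixels(denoise(img, p))
    b <- pixels(nlmDenoiseBrute(img, p))
    expect_lt(max(abs(f - b)), 1e-8 * diff(range(m)))
  }
})
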