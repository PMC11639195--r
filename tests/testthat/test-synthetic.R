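test_that("truth scenes are deterministic and respect the edge geometry", {
  spec <- sceneSpec(height = 200L, width = 200L, fieldLevel = 1,
                    edgePosition = 0.5, edgeAngle = 5,
                    vignetteSigma = 1e6, phantomMargin = 0L)
  a <- makeTruthScene(spec)
  b <- makeTruthScene(spec)
  expect_identical(pixels(a), pixels(b))

  # count occluded pixels against the analytic line equation
  H <- 200; W <- 200
  s <- tan(5 * pi / 180)
  expectZero <- 0L
  for (i in seq_len(H)) {
    xe <- 0.5 * W + s * (i - (H + 1) / 2)
    expectZero <- expectZero + sum(seq_len(W) > xe)
  }
  expect_identical(sum(pixels(a) == 0), as.integer(expectZero))
  expect_equal(mean(pixels(a) == 0), 0.5, tolerance = 0.02)

  # zero source -> all-zero image
  z <- makeTruthScene(sceneSpec(height = 32L, width = 32L, fieldLevel = 0))
  expect_true(all(pixels(z) == 0))

  # invariant violations rejected
  expect_error(sceneSpec(edgeAngle = 1), "edgeAngle")
  expect_error(sceneSpec(height = 0L), "height")
})

test_that("cumulative simulation is deterministic and mean-accurate", {
  truth <- cherenkovImage(matrix(10, 16, 16))
  nm <- noiseModel(readSigma = 0.5, impulseRate = 0,
                   temporalMedianWindow = 1L, spatialMedianSize = 1L,
                   subtractBackground = FALSE)
  acq <- acquisitionSpec(framesTruth = 10L, framesNoisy = 4L, seed = 5L)
  a <- simulateCumulative(truth, acq, nm)
  b <- simulateCumulative(truth, acq, nm)
  expect_identical(pixels(a), pixels(b))

  # all-zero truth with all noise sources off -> all-zero output
  z <- simulateCumulative(cherenkovImage(matrix(0, 8, 8)),
                          acquisitionSpec(framesNoisy = 1L, seed = 1L),
                          noiseModel(readSigma = 0, impulseRate = 0,
                                     temporalMedianWindow = 1L,
                                     spatialMedianSize = 1L))
  expect_true(all(pixels(z) == 0))

  # law of large numbers: Monte-Carlo mean of per-frame images matches the
  # expectation map within 3 standard errors per pixel
  reps <- 200L
  n <- 4L
  acc <- array(0, c(16, 16, reps))
  for (r in seq_len(reps)) {
    acq_r <- acquisitionSpec(framesTruth = n, framesNoisy = n,
                             seed = 1000L + r)
    acc[, , r] <- pixels(simulateCumulative(truth, acq_r, nm)) / n
  }
  mc_mean <- apply(acc, c(1, 2), mean)
  mc_se <- apply(acc, c(1, 2), sd) / sqrt(reps)
  expect_true(all(abs(mc_mean - pixels(truth)) <= 3.5 * mc_se + 1e-9))
})

test_that("impulse counts follow the binomial law and never lower a pixel", {
  truth <- cherenkovImage(matrix(0, 100, 100))
  p <- 0.02
  nm <- noiseModel(readSigma = 0, impulseRate = p, impulseAmp = c(50, 200),
                   temporalMedianWindow = 1L, spatialMedianSize = 1L,
                   subtractBackground = FALSE)
  acq <- acquisitionSpec(framesTruth = 1L, framesNoisy = 1L, seed = 99L)
  fr <- pixels(simulateCumulative(truth, acq, nm))
  hits <- sum(fr > 0)
  N <- 100 * 100
  expect_gt(hits, N * p - 4 * sqrt(N * p * (1 - p)))
  expect_lt(hits, N * p + 4 * sqrt(N * p * (1 - p)))
  # impulse amplitudes are nonnegative: every hit raised the pixel
  expect_true(all(fr >= 0))
  expect_true(all(fr[fr > 0] >= 50))
})

test_that("frames below the temporal window disable it with a warning", {
  truth <- cherenkovImage(matrix(5, 8, 8))
  nm <- noiseModel(temporalMedianWindow = 5L, spatialMedianSize = 1L,
                   impulseRate = 0)
  acq <- acquisitionSpec(framesTruth = 3L, framesNoisy = 3L, seed = 2L)
  expect_warning(simulateCumulative(truth, acq, nm), "temporal median")
})

test_that("datasets share scale, pitch and reproduce exactly at equal frames", {
  spec <- sceneSpec(height = 40L, width = 40L, phantomMargin = 4L)
  nm <- noiseModel(impulseRate = 0)
  acq <- acquisitionSpec(framesTruth = 6L, framesNoisy = 6L, seed = 7L)
  ds <- makeDataset(spec, acq, nm, truthMode = "simulate")
  expect_identical(pixels(ds$truth), pixels(ds$noisy))
  expect_identical(pixelPitch(ds$truth), pixelPitch(ds$noisy))

  # counting statistics: more frames -> higher PSNR, same seed stream
  spec <- sceneSpec(height = 64L, width = 64L, phantomMargin = 6L)
  mk <- function(frames) {
    acq <- acquisitionSpec(framesTruth = 1000L, framesNoisy = frames,
                           seed = 31L)
    makeDataset(spec, acq, nm)
  }
  d25 <- mk(25L); d50 <- mk(50L)
  expect_gt(psnr(d50$truth, d50$noisy), psnr(d25$truth, d25$noisy))
})

test_that("plateau noise variance falls monotonically with frame count", {
  spec <- sceneSpec(height = 96L, width = 96L, phantomMargin = 8L)
  nm <- noiseModel(impulseRate = 0)
  pr <- plateauRegion(spec)
  sub <- function(img) pixels(img)[pr[2]:(pr[2] + pr[4] - 1),
                                   pr[1]:(pr[1] + pr[3] - 1)]
  v <- vapply(c(10L, 25L, 60L), function(frames) {
    acq <- acquisitionSpec(framesTruth = 600L, framesNoisy = frames,
                           seed = 12L)
    ds <- makeDataset(spec, acq, nm)
    var(as.vector(sub(ds$noisy) - sub(ds$truth)))
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("no pixel is negative after summation and clipping", {
  spec <- sceneSpec(height = 32L, width = 32L, fieldLevel = 0.2,
                    backgroundLevel = 2)
  nm <- noiseModel(readSigma = 3, impulseRate = 0.01)
  acq <- acquisitionSpec(framesTruth = 50L, framesNoisy = 5L, seed = 3L)
  ds <- makeDataset(spec, acq, nm)
  expect_true(all(pixels(ds$noisy) >= 0))
  expect_true(all(pixels(ds$truth) >= 0))
})
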