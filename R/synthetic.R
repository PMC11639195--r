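#' @include accessors.R params.R
NULL

#' Construct a SceneSpec
#'
#' Defaults describe the study's standard 256 x 256 scene: a smooth beam
#' plateau of 2.2 expected photons/pixel/frame with gentle Gaussian vignette
#' falloff, a 12-pixel zero border emulating the phantom silhouette, and a
#' slanted occluder edge 5 degrees from vertical at 62% of the width. At the
#' default 9000-frame ground-truth accumulation the plateau reaches about
#' 2e4 summed counts, the intensity regime on which the published absolute
#' parameter ranges of the denoisers are meaningful.
#'
#' @param height,width image size in pixels.
#' @param fieldLevel plateau intensity, expected photons/pixel/frame.
#' @param backgroundLevel ambient per-frame offset (counts/frame).
#' @param edgeAngle occluder tilt, degrees from vertical, between 2 and 12.
#' @param edgePosition edge location as a fraction of width.
#' @param vignetteSigma Gaussian falloff scale (pixels).
#' @param phantomMargin zero-signal border (pixels).
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(height = 256L, width = 256L, fieldLevel = 2.2,
                      backgroundLevel = 0.15, edgeAngle = 5,
                      edgePosition = 0.62, vignetteSigma = 220,
                      phantomMargin = 12L)
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      fieldLevel = as.numeric(fieldLevel),
      backgroundLevel = as.numeric(backgroundLevel),
      edgeAngle = as.numeric(edgeAngle),
      edgePosition = as.numeric(edgePosition),
      vignetteSigma = as.numeric(vignetteSigma),
      phantomMargin = as.integer(phantomMargin))

#' Construct a NoiseModel
#'
#' Defaults emulate a low-light time-gated camera: sub-count read noise,
#' rare stray-radiation impulses bright enough to saturate locally relative
#' to the per-frame signal, and the camera-side preprocessing (temporal
#' median over 3 frames, 3 x 3 spatial median, background subtraction).
#'
#' @param readSigma Gaussian read-noise std per frame (counts).
#' @param impulseRate per-pixel per-frame impulse probability, <= 0.05.
#' @param impulseAmp numeric(2), uniform impulse amplitude bounds (counts).
#' @param temporalMedianWindow odd frame window, 1 disables.
#' @param spatialMedianSize odd kernel size, 1 disables.
#' @param subtractBackground subtract the configured background expectation
#'   (the generator stays analytic; per-frame estimation is out of scope).
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(readSigma = 0.6, impulseRate = 2e-4,
                       impulseAmp = c(50, 200), temporalMedianWindow = 3L,
                       spatialMedianSize = 3L, subtractBackground = TRUE)
  new("NoiseModel", readSigma = as.numeric(readSigma),
      impulseRate = as.numeric(impulseRate),
      impulseAmp = as.numeric(impulseAmp),
      temporalMedianWindow = as.integer(temporalMedianWindow),
      spatialMedianSize = as.integer(spatialMedianSize),
      subtractBackground = isTRUE(subtractBackground))

#' Construct an AcquisitionSpec
#'
#' MU level is proportional to frame count: `MU = frames * muPerFrame`.
#' The defaults mirror a 9000 MU ground-truth accumulation at 1 MU/frame
#' with a 25 MU-equivalent noisy accumulation.
#'
#' @param framesTruth ground-truth frame count.
#' @param framesNoisy noisy-accumulation frame count, <= framesTruth.
#' @param muPerFrame MU delivered per frame.
#' @param seed integer RNG seed of the dataset stream.
#' @return an [AcquisitionSpec-class].
#' @export
acquisitionSpec <- function(framesTruth = 9000L, framesNoisy = 25L,
                            muPerFrame = 1, seed = 1L)
  new("AcquisitionSpec", framesTruth = as.integer(framesTruth),
      framesNoisy = as.integer(framesNoisy),
      muPerFrame = as.numeric(muPerFrame), seed = as.integer(seed))

#' Noiseless per-frame expectation map of a scene
#'
#' Builds the deterministic truth scene: plateau intensity with Gaussian
#' vignette falloff about the image center, zero outside the phantom margin,
#' and zero on the occluded side of the slanted edge. The edge line passes
#' through `edgePosition * width` at the vertical center with a tilt of
#' `edgeAngle` degrees from vertical; a pixel is occluded when its column
#' center lies right of the line.
#'
#' @param spec a [SceneSpec-class].
#' @param pixelPitch mm per pixel (propagated to all downstream images).
#' @return a [CherenkovImage-class] of per-frame expected counts.
#' @examples
#' truth <- makeTruthScene(sceneSpec(height = 64L, width = 64L))
#' range(pixels(truth))
#' @export
makeTruthScene <- function(spec, pixelPitch = c(0.5, 0.5)) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  H <- spec@height; W <- spec@width
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  vig <- exp(-((rows - ci)^2 + (cols - cj)^2) / (2 * spec@vignetteSigma^2))
  px <- spec@fieldLevel * vig
  m <- spec@phantomMargin
  if (m > 0L) {
    border <- rows <= m | rows > H - m | cols <= m | cols > W - m
    px[border] <- 0
  }
  xEdge <- spec@edgePosition * W +
    tan(spec@edgeAngle * pi / 180) * (rows - ci)
  px[cols > xEdge] <- 0
  cherenkovImage(px, pixelPitch = pixelPitch,
                 metadata = list(scene = spec))
}

# counter-split per-frame seed: changing the frame count never reshuffles
# earlier frames
frame_seed <- function(seed, frame) {
  as.integer((as.numeric(seed) * 48271 + frame * 16807) %% 2147483629 + 1)
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Simulate a cumulative (frame-summed) acquisition
#'
#' For each frame, draws Poisson counts with mean `truth + backgroundLevel`,
#' adds Gaussian read noise and uniform-amplitude impulses at the configured
#' rate, then applies the camera preprocessing: rolling temporal median over
#' the frame axis (centered window, truncated at the sequence edges), spatial
#' median per frame, and subtraction of the known background expectation.
#' The preprocessed frames are summed and the sum clipped at zero.
#'
#' @param truth per-frame expectation map ([CherenkovImage-class]).
#' @param acq an [AcquisitionSpec-class]; `acq@seed` splits into per-frame
#'   substreams by counter.
#' @param noise a [NoiseModel-class].
#' @param backgroundLevel ambient per-frame offset added before the Poisson
#'   draw and subtracted by the camera when enabled (counts/frame).
#' @param frames number of frames to accumulate (default `acq@framesNoisy`).
#' @return a [CherenkovImage-class] of summed counts.
#' @export
simulateCumulative <- function(truth, acq, noise, backgroundLevel = 0,
                               frames = acq@framesNoisy) {
  stopifnot(is(truth, "CherenkovImage"), is(acq, "AcquisitionSpec"),
            is(noise, "NoiseModel"))
  validObject(acq); validObject(noise)
  mu <- truth@pixels + backgroundLevel
  if (any(!is.finite(mu))) stop("non-finite truth values")
  H <- nrow(mu); W <- ncol(mu); P <- H * W
  frames <- as.integer(frames)
  tw <- noise@temporalMedianWindow
  if (tw > 1L && frames < tw) {
    warning("frames < temporal median window; temporal median disabled")
    tw <- 1L
  }
  stack <- matrix(0, P, frames)
  with_preserved_rng({
    for (f in seq_len(frames)) {
      set.seed(frame_seed(acq@seed, f))
      fr <- rpois(P, as.vector(mu))
      if (noise@readSigma > 0) fr <- fr + rnorm(P, 0, noise@readSigma)
      if (noise@impulseRate > 0) {
        hit <- which(runif(P) < noise@impulseRate)
        if (length(hit))
          fr[hit] <- fr[hit] +
            runif(length(hit), noise@impulseAmp[1], noise@impulseAmp[2])
      }
      stack[, f] <- fr
    }
  })
  if (tw > 1L) stack <- .cpp_temporal_median(stack, tw)
  if (noise@spatialMedianSize > 1L)
    for (f in seq_len(frames))
      stack[, f] <- as.vector(
        .cpp_median2d(matrix(stack[, f], H, W), noise@spatialMedianSize))
  if (noise@subtractBackground) stack <- stack - backgroundLevel
  out <- matrix(pmax(rowSums(stack), 0), H, W)
  cherenkovImage(out, pixelPitch = truth@pixelPitch,
                 metadata = list(frames = frames, seed = acq@seed,
                                 noise = noise))
}

#' Generate a matched ground-truth / noisy image pair
#'
#' The ground truth is by default the analytic expectation map scaled by
#' `framesTruth` (flagged in metadata); `truthMode = "simulate"` accumulates
#' it stochastically instead. The noisy image accumulates `framesNoisy`
#' frames and is rescaled by `framesTruth / framesNoisy` so both images share
#' one intensity scale.
#'
#' @param spec a [SceneSpec-class].
#' @param acq an [AcquisitionSpec-class].
#' @param noise a [NoiseModel-class].
#' @param truthMode "analytic" (default) or "simulate".
#' @param pixelPitch mm per pixel.
#' @return list with elements `truth` and `noisy`, both
#'   [CherenkovImage-class] on the truth intensity scale.
#' @examples
#' ds <- makeDataset(sceneSpec(height = 48L, width = 48L, phantomMargin = 4L),
#'                   acquisitionSpec(framesTruth = 100L, framesNoisy = 10L),
#'                   noiseModel(impulseRate = 0))
#' psnr(ds$truth, ds$noisy)
#' @export
makeDataset <- function(spec, acq, noise, truthMode = c("analytic", "simulate"),
                        pixelPitch = c(0.5, 0.5)) {
  truthMode <- match.arg(truthMode)
  perFrame <- makeTruthScene(spec, pixelPitch)
  truth <- if (truthMode == "analytic") {
    cherenkovImage(perFrame@pixels * acq@framesTruth, pixelPitch = pixelPitch,
                   metadata = list(scene = spec, acq = acq,
                                   truthMode = "analytic"))
  } else {
    img <- simulateCumulative(perFrame, acq, noise,
                              backgroundLevel = spec@backgroundLevel,
                              frames = acq@framesTruth)
    img@metadata <- c(img@metadata, list(scene = spec, truthMode = "simulate"))
    img
  }
  noisy <- simulateCumulative(perFrame, acq, noise,
                              backgroundLevel = spec@backgroundLevel,
                              frames = acq@framesNoisy)
  scale <- acq@framesTruth / acq@framesNoisy
  noisy <- cherenkovImage(noisy@pixels * scale, pixelPitch = pixelPitch,
                          metadata = c(noisy@metadata,
                                       list(scene = spec, scale = scale,
                                            muEquivalent =
                                              acq@framesNoisy * acq@muPerFrame)))
  list(truth = truth, noisy = noisy)
}

#' The study's default scene set
#'
#' Five scenes varying edge tilt, edge position, plateau level and vignette
#' scale, mirroring a study in which several phantom/beam configurations
#' contribute images with different geometric, noise and intensity features.
#'
#' @param n number of scenes (recycled beyond 5).
#' @param height,width scene size in pixels.
#' @return list of [SceneSpec-class] objects.
#' @export
defaultScenes <- function(n = 5L, height = 256L, width = 256L) {
  angles <- c(5, 4, 7, 6, 8)
  posns <- c(0.62, 0.58, 0.66, 0.60, 0.64)
  levels <- c(2.2, 2.0, 2.5, 1.8, 2.4)
  vigs <- c(220, 200, 240, 180, 260)
  lapply(seq_len(n), function(i) {
    k <- (i - 1L) %% 5L + 1L
    sceneSpec(height = height, width = width, fieldLevel = levels[k],
              edgeAngle = angles[k], edgePosition = posns[k],
              vignetteSigma = vigs[k])
  })
}
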