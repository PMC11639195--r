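#' @include CherenkovDenoise-package.R
NULL

#' CherenkovImage: a 2D intensity image with physical pixel pitch
#'
#' The central container of the package: a nonnegative 2D grid of summed-count
#' intensities together with the physical size of one pixel in the object
#' plane (mm per pixel, per axis). All filters and metrics consume and return
#' this class; the pitch propagates untouched through every filter and feeds
#' the mm^-1 frequency axis of the noise power spectrum.
#'
#' @slot pixels numeric matrix of finite, nonnegative intensities.
#' @slot pixelPitch numeric(2), mm per pixel along (row, column); both > 0.
#' @slot metadata list of free-form provenance (generator specs, filter
#'   parameters, cost traces).
#' @aliases CherenkovImage
#' @exportClass CherenkovImage
setClass("CherenkovImage",
  representation(pixels = "matrix", pixelPitch = "numeric",
                 metadata = "list"),
  prototype(pixelPitch = c(0.5, 0.5), metadata = list()))

setValidity("CherenkovImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (any(!is.finite(p))) return("all pixel values must be finite")
  if (any(p < 0)) return("all pixel values must be >= 0")
  if (length(object@pixelPitch) != 2L || any(!is.finite(object@pixelPitch)) ||
      any(object@pixelPitch <= 0))
    return("pixelPitch must be two positive finite values (mm/pixel)")
  TRUE
})

#' SceneSpec: geometry and intensity of the synthetic truth scene
#'
#' Describes the noiseless per-frame expectation map: a smooth beam-field
#' plateau with Gaussian vignette falloff on a phantom silhouette, a zeroed
#' border, and a slanted occluder edge (the sharpness target). The edge angle
#' is constrained to 2-12 degrees from vertical because slanted-edge sharpness
#' estimation assumes a near-vertical tilted edge.
#'
#' @slot height,width image size in pixels.
#' @slot fieldLevel plateau intensity, expected photons/pixel/frame (> 0
#'   unless deliberately zero for degenerate tests).
#' @slot backgroundLevel ambient per-frame offset (counts/frame).
#' @slot edgeAngle occluder edge tilt, degrees from vertical, between 2
#'   and 12.
#' @slot edgePosition edge location as a fraction of image width.
#' @slot vignetteSigma Gaussian falloff scale in pixels.
#' @slot phantomMargin zero-signal border width in pixels.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(height = "integer", width = "integer",
                 fieldLevel = "numeric", backgroundLevel = "numeric",
                 edgeAngle = "numeric", edgePosition = "numeric",
                 vignetteSigma = "numeric", phantomMargin = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@height < 1L || object@width < 1L)
    return("height and width must be >= 1")
  if (object@fieldLevel < 0) return("fieldLevel must be >= 0")
  if (object@backgroundLevel < 0) return("backgroundLevel must be >= 0")
  if (object@edgeAngle < 2 || object@edgeAngle > 12)
    return("edgeAngle must lie in [2, 12] degrees (near-vertical slanted edge)")
  if (object@edgePosition <= 0 || object@edgePosition >= 1)
    return("edgePosition must be a fraction of width in (0, 1)")
  if (object@vignetteSigma <= 0) return("vignetteSigma must be > 0")
  if (object@phantomMargin < 0L) return("phantomMargin must be >= 0")
  TRUE
})

#' NoiseModel: per-frame stochastic camera model
#'
#' Parameters of the simulated acquisition chain: Gaussian read noise and
#' stray-radiation impulses added to the Poisson shot noise of each frame,
#' followed by the camera-side preprocessing (rolling temporal median,
#' per-frame spatial median, background subtraction).
#'
#' @slot readSigma std of additive Gaussian read noise per frame (counts).
#' @slot impulseRate per-pixel per-frame probability of an impulse, at
#'   most 0.05.
#' @slot impulseAmp numeric(2), uniform amplitude bounds of impulses (counts,
#'   nonnegative so an impulse never lowers a raw value).
#' @slot temporalMedianWindow odd frame count for the camera temporal median
#'   (1 disables).
#' @slot spatialMedianSize odd kernel size for the camera spatial median
#'   (1 disables).
#' @slot subtractBackground subtract the configured background expectation.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(readSigma = "numeric", impulseRate = "numeric",
                 impulseAmp = "numeric", temporalMedianWindow = "integer",
                 spatialMedianSize = "integer",
                 subtractBackground = "logical"))

setValidity("NoiseModel", function(object) {
  if (object@readSigma < 0) return("readSigma must be >= 0")
  if (object@impulseRate < 0 || object@impulseRate > 0.05)
    return("impulseRate must lie in [0, 0.05]")
  if (length(object@impulseAmp) != 2L || any(object@impulseAmp < 0) ||
      object@impulseAmp[1] > object@impulseAmp[2])
    return("impulseAmp must be nonnegative bounds lo <= hi")
  for (w in c(object@temporalMedianWindow, object@spatialMedianSize))
    if (w < 1L || w %% 2L == 0L)
      return("median windows must be odd and >= 1 (1 = disabled)")
  TRUE
})

#' AcquisitionSpec: frame counts and seed of one simulated delivery
#'
#' Noise level is controlled by the number of summed frames, proportional to
#' delivered monitor units (MU): MU = frames * muPerFrame.
#'
#' @slot framesTruth frame count of the ground-truth accumulation.
#' @slot framesNoisy frame count of the noisy accumulation (<= framesTruth).
#' @slot muPerFrame MU delivered per frame.
#' @slot seed integer RNG seed; frames draw from counter-split substreams so
#'   changing the frame count never reshuffles earlier frames.
#' @exportClass AcquisitionSpec
setClass("AcquisitionSpec",
  representation(framesTruth = "integer", framesNoisy = "integer",
                 muPerFrame = "numeric", seed = "integer"))

setValidity("AcquisitionSpec", function(object) {
  if (object@framesTruth < 1L || object@framesNoisy < 1L)
    return("frame counts must be >= 1")
  if (object@framesNoisy > object@framesTruth)
    return("framesNoisy must be <= framesTruth")
  if (object@muPerFrame <= 0) return("muPerFrame must be > 0")
  TRUE
})

#' DenoiseParams and its five concrete parameter classes
#'
#' One parameter record per denoiser. Construct with [tvParams()],
#' [nlmParams()], [bm3dParams()], [atmParams()] or [bilateralParams()];
#' dispatch through [denoise()].
#'
#' @aliases TVParams NLMParams BM3DParams ATMParams BilateralParams
#' @exportClass DenoiseParams
setClass("DenoiseParams", representation("VIRTUAL"))

#' @exportClass TVParams
setClass("TVParams", contains = "DenoiseParams",
  representation(lambda = "numeric", nIter = "integer"))

setValidity("TVParams", function(object) {
  if (!is.finite(object@lambda) || object@lambda < 0)
    return("lambda must be finite and >= 0")
  if (object@nIter < 0L) return("nIter must be >= 0")
  TRUE
})

#' @exportClass NLMParams
setClass("NLMParams", contains = "DenoiseParams",
  representation(sigma = "numeric", window = "integer", patch = "integer"))

setValidity("NLMParams", function(object) {
  if (!is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be > 0")
  if (object@patch < 1L) return("patch must be >= 1")
  if (object@window < object@patch) return("window must be >= patch")
  TRUE
})

#' @exportClass BM3DParams
setClass("BM3DParams", contains = "DenoiseParams",
  representation(noiseSigma = "numeric", gamma = "numeric",
                 blockSize = "integer", maxGroup = "integer",
                 lambdaThr = "numeric", mu = "numeric",
                 searchWindow = "integer", step = "integer"))

setValidity("BM3DParams", function(object) {
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!object@blockSize %in% c(4L, 8L)) return("blockSize must be 4 or 8")
  m <- object@maxGroup
  if (m < 1L || bitwAnd(m, m - 1L) != 0L)
    return("maxGroup must be a power of 2")
  if (object@lambdaThr <= 0 || object@mu <= 0)
    return("lambdaThr and mu must be > 0")
  if (object@searchWindow < object@blockSize)
    return("searchWindow must be >= blockSize")
  if (object@step < 1L) return("step must be >= 1")
  TRUE
})

#' @exportClass ATMParams
setClass("ATMParams", contains = "DenoiseParams",
  representation(beta = "integer", lambda = "numeric", delta = "numeric"))

setValidity("ATMParams", function(object) {
  if (object@lambda < 2) return("lambda must be >= 2 (so alpha <= 0.5)")
  if (object@beta < 3L || object@beta %% 2L == 0L)
    return("beta must be odd and >= 3")
  if (object@delta < 0) return("delta must be >= 0")
  TRUE
})

#' @exportClass BilateralParams
setClass("BilateralParams", contains = "DenoiseParams",
  representation(sigmaS = "numeric", sigmaR = "numeric", window = "integer"))

setValidity("BilateralParams", function(object) {
  if (object@sigmaS <= 0 || object@sigmaR <= 0)
    return("sigmaS and sigmaR must be > 0")
  if (object@window < 1L || object@window %% 2L == 0L)
    return("window must be odd and >= 1")
  TRUE
})

#' ESFCurve: oversampled edge spread function
#'
#' The profile of a slanted edge, projected onto the edge-normal axis and
#' binned at sub-pixel resolution.
#'
#' @slot positions strictly increasing sub-pixel distances from the fitted
#'   edge (pixels).
#' @slot values oversampled edge profile intensities.
#' @slot oversampling bins per pixel.
#' @slot edgeAngle fitted edge tilt, degrees from vertical.
#' @exportClass ESFCurve
setClass("ESFCurve",
  representation(positions = "numeric", values = "numeric",
                 oversampling = "numeric", edgeAngle = "numeric"))

setValidity("ESFCurve", function(object) {
  if (length(object@positions) != length(object@values))
    return("positions and values must have equal length")
  if (any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' MTFCurve: modulation transfer function
#'
#' Normalized Fourier magnitude of the line spread function, on a spatial
#' frequency axis in cycles/pixel from 0 to Nyquist (0.5).
#'
#' @slot freqs spatial frequencies (cycles/pixel), from 0 to 0.5.
#' @slot values modulation, equal to 1 at zero frequency.
#' @exportClass MTFCurve
setClass("MTFCurve",
  representation(freqs = "numeric", values = "numeric"))

setValidity("MTFCurve", function(object) {
  if (length(object@freqs) != length(object@values))
    return("freqs and values must have equal length")
  if (abs(object@values[1] - 1) > 1e-12)
    return("values must be normalized to 1 at zero frequency")
  if (object@freqs[1] != 0 || max(object@freqs) > 0.5 + 1e-12)
    return("freqs must run from 0 to at most 0.5 cycles/pixel")
  TRUE
})

#' NPSResult: 2D and radially averaged noise power spectrum
#'
#' @slot nps2d 2D spectrum, counts^2 mm^2, DC at the matrix center.
#' @slot radialFreqs radial spatial frequencies (mm^-1).
#' @slot radialValues per-bin mean over the per-ROI radial profiles.
#' @slot radialStd per-bin standard deviation across ROIs.
#' @slot binCounts number of 2D frequency samples per radial bin.
#' @slot roiSize ROI side in pixels.
#' @slot nRois number of (overlapping) ROIs averaged.
#' @slot pixelPitch mm per pixel, per axis.
#' @exportClass NPSResult
setClass("NPSResult",
  representation(nps2d = "matrix", radialFreqs = "numeric",
                 radialValues = "numeric", radialStd = "numeric",
                 binCounts = "numeric", roiSize = "integer",
                 nRois = "integer", pixelPitch = "numeric"))

setValidity("NPSResult", function(object) {
  if (any(object@nps2d < -1e-12)) return("nps2d must be >= 0 everywhere")
  if (any(object@radialStd < 0)) return("radialStd must be >= 0")
  if (object@nRois < 2L) return("nRois must be >= 2")
  TRUE
})

#' SweepGrid: parameter axes for one filter's PSNR sweep
#'
#' @slot filterId one of "tvl1", "nlm", "bm3d", "atm", "bilateral".
#' @slot axes named list of numeric parameter value vectors.
#' @slot fixed named list of parameters held fixed across the grid.
#' @exportClass SweepGrid
setClass("SweepGrid",
  representation(filterId = "character", axes = "list", fixed = "list"))

setValidity("SweepGrid", function(object) {
  if (!object@filterId %in% c("tvl1", "nlm", "bm3d", "atm", "bilateral"))
    return("unknown filterId")
  if (length(object@axes) == 0L || any(!vapply(object@axes, length, 1L)))
    return("every axis must be non-empty")
  if (is.null(names(object@axes)) || any(names(object@axes) == ""))
    return("axes must be named")
  TRUE
})

#' SweepResult: the trace and argmax of a PSNR parameter sweep
#'
#' @slot filterId the swept filter.
#' @slot trace data.frame of grid points with their PSNR (dB; NA where the
#'   filter failed).
#' @slot bestParams the PSNR-maximizing parameter record.
#' @slot bestPsnr maximal PSNR (dB).
#' @slot noisyPsnr PSNR of the unfiltered image (dB).
#' @slot percentIncrease 100 * (bestPsnr - noisyPsnr) / noisyPsnr.
#' @slot boundary TRUE when the argmax sits on a grid boundary.
#' @exportClass SweepResult
setClass("SweepResult",
  representation(filterId = "character", trace = "data.frame",
                 bestParams = "DenoiseParams", bestPsnr = "numeric",
                 noisyPsnr = "numeric", percentIncrease = "numeric",
                 boundary = "logical"))

setValidity("SweepResult", function(object) {
  ps <- object@trace$psnr
  if (all(is.na(ps))) return("trace holds no successful evaluation")
  if (!isTRUE(all.equal(object@bestPsnr, max(ps, na.rm = TRUE),
                        tolerance = 1e-12)))
    return("bestPsnr must equal the maximal trace PSNR")
  expected <- 100 * (object@bestPsnr - object@noisyPsnr) / object@noisyPsnr
  if (!isTRUE(all.equal(object@percentIncrease, expected,
                        tolerance = 1e-10)))
    return("percentIncrease inconsistent with bestPsnr/noisyPsnr")
  TRUE
})

#' BenchmarkConfig: the full-study configuration
#'
#' @slot scenes list of [SceneSpec-class] objects (one synthetic image each).
#' @slot noise the shared [NoiseModel-class].
#' @slot muLevels MU-equivalent noise levels to test.
#' @slot filters filter ids to run.
#' @slot gridPoints sweep grid density per axis for the 1D sweeps.
#' @slot bilateralGridPoints per-axis density of the bilateral 2D sweep.
#' @slot npsRoiSize ROI side for the NPS of each image.
#' @slot framesTruth,muPerFrame acquisition scale (MU = frames * muPerFrame).
#' @slot masterSeed integer master seed; scene i uses masterSeed + i.
#' @slot withStats run ANOVA/Tukey across filters (needs >= 2 scenes).
#' @slot outDir optional output directory ("" disables file output).
#' @exportClass BenchmarkConfig
setClass("BenchmarkConfig",
  representation(scenes = "list", noise = "NoiseModel", muLevels = "numeric",
                 filters = "character", gridPoints = "integer",
                 bilateralGridPoints = "integer", npsRoiSize = "integer",
                 framesTruth = "integer", muPerFrame = "numeric",
                 masterSeed = "integer", withStats = "logical",
                 outDir = "character"))

setValidity("BenchmarkConfig", function(object) {
  if (!all(vapply(object@scenes, is, TRUE, "SceneSpec")))
    return("scenes must be a list of SceneSpec objects")
  if (any(!object@filters %in% c("tvl1", "nlm", "bm3d", "atm", "bilateral")))
    return("unknown filter id")
  if (object@withStats && length(object@scenes) < 2L)
    return("statistics require >= 2 images per MU level")
  if (any(object@muLevels <= 0)) return("muLevels must be > 0")
  TRUE
})

#' BenchmarkReport: per-image, per-filter metrics plus comparison statistics
#'
#' @slot metrics data.frame with one row per (scene, MU, filter): best
#'   parameters, noisy and denoised PSNR, percent increase, MTF50/MTF10,
#'   10-90 rise distance, mean NPS over 0-1.5 mm^-1.
#' @slot anova data.frame per MU level: one-way ANOVA F and p across filters
#'   on percent PSNR increase.
#' @slot tukey list per MU level of pairwise Tukey HSD tables.
#' @slot sweeps list of sweep traces keyed "scene<i>_mu<level>_<filter>".
#' @slot nps list of [NPSResult-class] objects keyed "scene<i>_mu<level>_<filter|noisy>".
#' @slot config the generating [BenchmarkConfig-class].
#' @slot schemaVersion report schema version string.
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
  representation(metrics = "data.frame", anova = "data.frame",
                 tukey = "list", sweeps = "list", nps = "list",
                 config = "BenchmarkConfig", schemaVersion = "character"))
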