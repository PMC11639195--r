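#' @include AllClasses.R
NULL

#' Extract the pixel matrix of an image
#' @param x a [CherenkovImage-class].
#' @return numeric matrix of intensities.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Physical pixel pitch (mm per pixel, per axis)
#' @param x a [CherenkovImage-class] or [NPSResult-class].
#' @return numeric(2).
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' Provenance metadata attached to an object
#' @param x a [CherenkovImage-class].
#' @return a list.
#' @export
setGeneric("imageMetadata", function(x) standardGeneric("imageMetadata"))

#' Apply a denoising filter to an image
#'
#' Dispatches on the class of `params`: `TVParams` runs the TV-L1
#' primal-dual minimization, `NLMParams` the fast non-local means,
#' `BM3DParams` the two-stage BM3D collaborative filter, `ATMParams` the 2D
#' adaptive alpha-trimmed mean and `BilateralParams` the bilateral filter.
#' Every method preserves the
#' image shape and pixel pitch and records its parameters in the result's
#' metadata.
#'
#' @param img a [CherenkovImage-class].
#' @param params a [DenoiseParams-class] subclass.
#' @param ... method-specific options.
#' @return the denoised [CherenkovImage-class].
#' @seealso [tvParams()], [nlmParams()], [bm3dParams()], [atmParams()],
#'   [bilateralParams()], [sweepFilter()]
#' @export
setGeneric("denoise", function(img, params, ...) standardGeneric("denoise"))

#' Identifier of the filter a parameter record belongs to
#' @param params a [DenoiseParams-class] subclass.
#' @return one of "tvl1", "nlm", "bm3d", "atm", "bilateral".
#' @export
setGeneric("filterId", function(params) standardGeneric("filterId"))
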