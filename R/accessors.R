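#' @include AllGenerics.R
NULL

#' Construct a CherenkovImage
#'
#' @param pixels numeric matrix of finite, nonnegative intensities
#'   (arbitrary summed-count units).
#' @param pixelPitch mm per pixel in the object plane, recycled to both axes.
#'   The default 0.5 mm/pixel is a configured convention, not a measured
#'   value; every NPS result carries the pitch it was computed with.
#' @param metadata optional provenance list.
#' @return a [CherenkovImage-class].
#' @examples
#' img <- cherenkovImage(matrix(1:12, 3, 4), pixelPitch = 0.5)
#' dim(pixels(img))
#' @export
cherenkovImage <- function(pixels, pixelPitch = c(0.5, 0.5),
                           metadata = list()) {
  if (length(pixelPitch) == 1L) pixelPitch <- rep(pixelPitch, 2L)
  new("CherenkovImage", pixels = as.matrix(pixels),
      pixelPitch = as.numeric(pixelPitch), metadata = metadata)
}

#' @rdname pixels
#' @export
setMethod("pixels", "CherenkovImage", function(x) x@pixels)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "CherenkovImage", function(x) x@pixelPitch)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "NPSResult", function(x) x@pixelPitch)

#' @rdname imageMetadata
#' @export
setMethod("imageMetadata", "CherenkovImage", function(x) x@metadata)

setMethod("show", "CherenkovImage", function(object) {
  p <- object@pixels
  cat(sprintf("CherenkovImage: %d x %d pixels, pitch %.3g x %.3g mm\n",
              nrow(p), ncol(p), object@pixelPitch[1], object@pixelPitch[2]))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(p), max(p), mean(p)))
  if (length(object@metadata))
    cat("  metadata fields:", paste(names(object@metadata), collapse = ", "),
        "\n")
  invisible(NULL)
})

setMethod("show", "ESFCurve", function(object) {
  cat(sprintf(
    "ESFCurve: %d bins at %gx oversampling, edge angle %.2f deg\n",
    length(object@positions), object@oversampling, object@edgeAngle))
  invisible(NULL)
})

setMethod("show", "MTFCurve", function(object) {
  s <- mtfSummary(object)
  cat(sprintf("MTFCurve: %d frequencies up to %.3f cycles/pixel\n",
              length(object@freqs), max(object@freqs)))
  cat(sprintf("  MTF50 = %s, MTF10 = %s cycles/pixel\n",
              format(s$mtf50, digits = 3), format(s$mtf10, digits = 3)))
  invisible(NULL)
})

setMethod("show", "NPSResult", function(object) {
  cat(sprintf(
    "NPSResult: %d x %d ROIs of %d px, %d radial bins, pitch %.3g mm\n",
    object@nRois, object@roiSize, object@roiSize,
    length(object@radialFreqs), object@pixelPitch[1]))
  cat(sprintf("  mean 2D NPS %.4g counts^2 mm^2\n", mean(object@nps2d)))
  invisible(NULL)
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult [%s]: %d grid points\n", object@filterId,
              nrow(object@trace)))
  cat(sprintf("  noisy PSNR %.2f dB -> best %.2f dB (+%.2f%%)%s\n",
              object@noisyPsnr, object@bestPsnr, object@percentIncrease,
              if (object@boundary) " [boundary argmax]" else ""))
  invisible(NULL)
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport (schema %s): %d metric rows\n",
              object@schemaVersion, nrow(object@metrics)))
  if (nrow(object@anova))
    for (i in seq_len(nrow(object@anova)))
      cat(sprintf("  ANOVA @ %g MU: F = %.3f, p = %.4f\n",
                  object@anova$mu[i], object@anova$F[i], object@anova$p[i]))
  invisible(NULL)
})

# internal: accept a CherenkovImage or plain matrix
as_pixels <- function(x) {
  if (is(x, "CherenkovImage")) x@pixels else as.matrix(x)
}

# internal: rebuild an image from filtered pixels, propagating pitch
rewrap <- function(img, px, extra = list()) {
  new("CherenkovImage", pixels = px, pixelPitch = img@pixelPitch,
      metadata = c(img@metadata[setdiff(names(img@metadata),
                                        names(extra))], extra))
}
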