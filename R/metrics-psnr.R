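#' @include accessors.R
NULL

#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(peak / RMSE)` with the RMSE taken over all pixels. The
#' peak is by default the maximum of the ground-truth image (the formula's
#' reading); `peak = "value"` with `peakValue` substitutes a data-type
#' maximum instead (the two readings differ; choose explicitly).
#'
#' @param truth ground-truth image ([CherenkovImage-class] or matrix).
#' @param test noisy or denoised image of identical shape.
#' @param peak "truth" (default: `max(truth)`) or "value".
#' @param peakValue the peak when `peak = "value"`.
#' @return PSNR in dB; `+Inf` when the images are identical.
#' @examples
#' t <- matrix(c(0, 100, 100, 0), 2)
#' x <- t; x[1] <- 10
#' psnr(t, x)  # 20 log10(100 / 5) = 26.02 dB
#' @export
psnr <- function(truth, test, peak = c("truth", "value"), peakValue = NULL) {
  peak <- match.arg(peak)
  x <- as_pixels(truth)
  y <- as_pixels(test)
  if (!identical(dim(x), dim(y))) stop("images must have identical shapes")
  pk <- if (peak == "truth") max(x) else as.numeric(peakValue)
  if (!isTRUE(pk > 0)) stop("undefined peak: ground truth maximum must be > 0")
  rmse <- sqrt(mean((x - y)^2))
  if (rmse == 0) return(Inf)
  20 * log10(pk / rmse)
}
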