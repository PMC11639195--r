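#' @include AllGenerics.R
NULL

#' TV-L1 parameters
#'
#' The TV-L1 objective is `||grad I||_2 + lambda ||I - G||_1`: the first term
#' penalizes total variation, the second keeps the estimate close to the
#' observed image. Larger `lambda` weights fidelity (lambda -> Inf recreates
#' the input); smaller `lambda` smooths harder.
#'
#' @param lambda regularization coefficient, >= 0. Scale-free: both objective
#'   terms scale linearly with intensity.
#' @param nIter primal-dual iteration count (default 100).
#' @return a `TVParams` parameter record.
#' @export
tvParams <- function(lambda, nIter = 100L)
  new("TVParams", lambda = as.numeric(lambda), nIter = as.integer(nIter))

#' Non-local means parameters
#'
#' `window` and `patch` follow the "20 x 20 search window, 4 x 4 patch"
#' convention: both are even full sizes interpreted as centered half-sizes
#' (window/2 and patch/2), giving effective odd supports of window+1 and
#' patch+1 pixels. `sigma` sets the denoising aggressiveness; patch
#' squared-distances are divided by sigma^2 without window-size
#' normalization, so sigma lives on the intensity (count) scale.
#'
#' @param sigma denoising aggressiveness (counts), > 0.
#' @param window search-window full side in pixels (default 20).
#' @param patch patch full side in pixels (default 4).
#' @return an `NLMParams` parameter record.
#' @export
nlmParams <- function(sigma, window = 20L, patch = 4L)
  new("NLMParams", sigma = as.numeric(sigma), window = as.integer(window),
      patch = as.integer(patch))

#' BM3D parameters
#'
#' Assumes a white-Gaussian noise power spectral density with standard
#' deviation `noiseSigma`. `gamma` is the matching-bias weight of the
#' block-distance (3 in the hard-threshold stage; the Wiener stage always
#' re-matches with gamma = 0). The remaining arguments are the standard
#' published defaults of the reference method: 2D orthonormal DCT on 8x8
#' blocks, 1D Haar across groups of up to 16 blocks, hard-threshold
#' multiplier 2.7, Wiener regularizer 1, 39-pixel matching neighborhood.
#'
#' @param noiseSigma assumed noise std (counts), >= 0 (0 = identity).
#' @param gamma stage-1 matching-bias weight (default 3).
#' @param blockSize block side in pixels, 4 or 8.
#' @param maxGroup maximum matched blocks per group (power of 2).
#' @param lambdaThr hard-threshold multiplier.
#' @param mu Wiener regularizer.
#' @param searchWindow matching neighborhood side in pixels.
#' @param step reference-block stride in pixels.
#' @return a `BM3DParams` parameter record.
#' @export
bm3dParams <- function(noiseSigma, gamma = 3, blockSize = 8L,
                       maxGroup = 16L, lambdaThr = 2.7, mu = 1,
                       searchWindow = 39L, step = 3L)
  new("BM3DParams", noiseSigma = as.numeric(noiseSigma),
      gamma = as.numeric(gamma), blockSize = as.integer(blockSize),
      maxGroup = as.integer(maxGroup), lambdaThr = as.numeric(lambdaThr),
      mu = as.numeric(mu), searchWindow = as.integer(searchWindow),
      step = as.integer(step))

#' Adaptive alpha-trimmed mean parameters
#'
#' Low-signal pixels (photon-starved, noisiest) receive the largest window
#' `beta` and no trimming; bright pixels receive small windows with trimming
#' up to the median. `lambda >= 2` guarantees the trimming fraction alpha
#' never exceeds 0.5. Signal below `delta` counts is treated as camera noise
#' and always given the maximum window.
#'
#' @param lambda aggressiveness, >= 2; larger values push the window toward
#'   beta everywhere and reduce trimming.
#' @param beta maximum window side in pixels, odd (default 31).
#' @param delta low-signal cutoff in counts (default 5).
#' @return an `ATMParams` parameter record.
#' @export
atmParams <- function(lambda, beta = 31L, delta = 5)
  new("ATMParams", beta = as.integer(beta), lambda = as.numeric(lambda),
      delta = as.numeric(delta))

#' Bilateral filter parameters
#'
#' @param sigmaS geometric closeness scale (pixels).
#' @param sigmaR intensity similarity scale (counts).
#' @param window support side in pixels; default `2 * ceiling(2 * sigmaS) + 1`.
#' @return a `BilateralParams` parameter record.
#' @export
bilateralParams <- function(sigmaS, sigmaR,
                            window = 2L * as.integer(ceiling(2 * sigmaS)) + 1L)
  new("BilateralParams", sigmaS = as.numeric(sigmaS),
      sigmaR = as.numeric(sigmaR), window = as.integer(window))

#' @rdname filterId
#' @export
setMethod("filterId", "TVParams", function(params) "tvl1")
#' @rdname filterId
#' @export
setMethod("filterId", "NLMParams", function(params) "nlm")
#' @rdname filterId
#' @export
setMethod("filterId", "BM3DParams", function(params) "bm3d")
#' @rdname filterId
#' @export
setMethod("filterId", "ATMParams", function(params) "atm")
#' @rdname filterId
#' @export
setMethod("filterId", "BilateralParams", function(params) "bilateral")

# internal: build a parameter record from one sweep grid point
# (the bilateral grid sweeps the range variance sigmaR2 = sigmaR^2)
params_from_point <- function(filter_id, point, fixed = list()) {
  args <- c(as.list(point), fixed)
  if (!is.null(args$sigmaR2)) {
    args$sigmaR <- sqrt(args$sigmaR2)
    args$sigmaR2 <- NULL
  }
  switch(filter_id,
    tvl1 = do.call(tvParams, args),
    nlm = do.call(nlmParams, args),
    bm3d = do.call(bm3dParams, args),
    atm = do.call(atmParams, args),
    bilateral = do.call(bilateralParams, args),
    stop("unknown filter id: ", filter_id))
}

# internal: the swept parameters of a record, as a named list
swept_values <- function(params) {
  switch(filterId(params),
    tvl1 = list(lambda = params@lambda),
    nlm = list(sigma = params@sigma),
    bm3d = list(noiseSigma = params@noiseSigma),
    atm = list(lambda = params@lambda),
    bilateral = list(sigmaS = params@sigmaS, sigmaR = params@sigmaR))
}
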