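#' @include accessors.R params.R
NULL

# forward differences with Neumann boundary (last row/col gradient 0)
tv_grad <- function(x) {
  H <- nrow(x); W <- ncol(x)
  gx <- cbind(x[, -1, drop = FALSE] - x[, -W, drop = FALSE], rep(0, H))
  gy <- rbind(x[-1, , drop = FALSE] - x[-H, , drop = FALSE], rep(0, W))
  list(gx = gx, gy = gy)
}

# negative adjoint of tv_grad (discrete divergence)
tv_div <- function(px, py) {
  H <- nrow(px); W <- ncol(px)
  dx <- px
  if (W > 1L) {
    dx[, 2:W] <- px[, 2:W] - px[, 1:(W - 1)]
    dx[, W] <- -px[, W - 1]
  }
  dy <- py
  if (H > 1L) {
    dy[2:H, ] <- py[2:H, ] - py[1:(H - 1), ]
    dy[H, ] <- -py[H - 1, ]
  }
  dx + dy
}

tv_cost <- function(x, g, lambda) {
  gr <- tv_grad(x)
  sum(sqrt(gr$gx^2 + gr$gy^2)) + lambda * sum(abs(x - g))
}

#' TV-L1 denoising by primal-dual minimization
#'
#' Minimizes `||grad I||_2 + lambda ||I - G||_1` (isotropic total variation
#' with an L1 fidelity term) by a primal-dual saddle-point scheme with
#' primal step 0.25 and dual step 0.125, the standard stable choice for the
#' forward-difference gradient operator. The objective value is logged every
#' iteration; a monotone safeguard returns the best-cost iterate so the
#' logged cost never increases (the raw saddle-point iterates drive the dual
#' updates). With `nIter = 0` the input is returned unchanged.
#'
#' The cost trace is stored in the result metadata as `tvCostTrace`
#' (element 1 = cost of the input) and the final value as `tvCost`.
#'
#' @param img a [CherenkovImage-class].
#' @param params a `TVParams` record.
#' @param ... unused.
#' @return the denoised image, clipped at zero.
#' @rdname denoise
#' @export
setMethod("denoise", signature("CherenkovImage", "TVParams"),
  function(img, params, ...) {
    validObject(params)
    g0 <- img@pixels
    if (params@nIter == 0L)
      return(rewrap(img, g0, list(filterParams = params,
                                  tvCostTrace = tv_cost(g0, g0, params@lambda))))
    # the minimizer is scale covariant (both terms are 1-homogeneous), so
    # iterate on the max-normalized image: the fixed step sizes are sized
    # for unit-scale data, and the cost trace rescales exactly
    scl <- max(g0, 1e-300)
    g <- g0 / scl
    lam <- params@lambda
    tau <- 0.25; sigma <- 0.125
    x <- g; xbar <- g
    px <- matrix(0, nrow(g), ncol(g)); py <- px
    best <- g; bestCost <- tv_cost(g, g, lam)
    trace <- numeric(params@nIter + 1L)
    trace[1L] <- bestCost
    thr <- tau * lam
    for (it in seq_len(params@nIter)) {
      gr <- tv_grad(xbar)
      px <- px + sigma * gr$gx
      py <- py + sigma * gr$gy
      nrm <- pmax(1, sqrt(px^2 + py^2))
      px <- px / nrm; py <- py / nrm
      xt <- x + tau * tv_div(px, py)
      d <- xt - g
      xn <- g + sign(d) * pmax(abs(d) - thr, 0)
      xbar <- 2 * xn - x
      x <- xn
      cst <- tv_cost(x, g, lam)
      if (cst <= bestCost) {
        bestCost <- cst
        best <- x
      }
      trace[it + 1L] <- bestCost
    }
    rewrap(img, pmax(best * scl, 0),
           list(filterParams = params, tvCost = bestCost * scl,
                tvCostTrace = trace * scl))
  })

#' Fast non-local means
#'
#' Integral-image formulation: for every shift within the search window the
#' summed squared-difference plane gives each site's patch distance in O(1);
#' the per-shift weight plane `exp(-ssd / sigma^2)` accumulates the shifted
#' image into a normalized weighted average. Uniform patch kernel; the
#' self-shift enters with weight 1. Values match the brute-force oracle
#' ([nlmDenoiseBrute()]) to machine precision.
#'
#' @rdname denoise
#' @export
setMethod("denoise", signature("CherenkovImage", "NLMParams"),
  function(img, params, ...) {
    validObject(params)
    hw <- params@window %/% 2L
    hp <- params@patch %/% 2L
    out <- .cpp_nlm_fast(img@pixels, params@sigma, hw, hp)
    rewrap(img, out, list(filterParams = params))
  })

#' Brute-force non-local means (reference oracle)
#'
#' Literal double loop over sites and window offsets evaluating the weighted
#' patch average directly. By default the patch kernel is uniform, matching
#' the fast path; `gaussKernel = TRUE` enables the Gaussian-weighted patch
#' variant of the original formulation (oracle only).
#'
#' @param img a [CherenkovImage-class].
#' @param params an `NLMParams` record.
#' @param gaussKernel use a Gaussian patch kernel instead of uniform.
#' @param gaussSigma std of the Gaussian patch kernel (pixels).
#' @return the denoised [CherenkovImage-class].
#' @export
nlmDenoiseBrute <- function(img, params, gaussKernel = FALSE,
                            gaussSigma = 1) {
  stopifnot(is(img, "CherenkovImage"), is(params, "NLMParams"))
  validObject(params)
  hw <- params@window %/% 2L
  hp <- params@patch %/% 2L
  out <- .cpp_nlm_brute(img@pixels, params@sigma, hw, hp, gaussKernel,
                        gaussSigma)
  rewrap(img, out, list(filterParams = params, bruteForce = TRUE))
}

#' Two-stage BM3D
#'
#' Stage 1 matches blocks on the noisy image (bias weight `gamma`), applies
#' the 3D transform (2D DCT per block, 1D Haar across the group), hard
#' thresholds at `lambdaThr * noiseSigma`, inverts and aggregates with
#' variance weights. Stage 2 re-matches on the stage-1 estimate (gamma = 0)
#' and replaces the threshold with Wiener shrinkage driven by the stage-1
#' coefficients. `noiseSigma = 0` returns the input unchanged (zero
#' threshold keeps all coefficients; Wiener gains tend to 1). The stage-1
#' image is stored in the result metadata as `bm3dStage1`.
#'
#' @rdname denoise
#' @export
setMethod("denoise", signature("CherenkovImage", "BM3DParams"),
  function(img, params, ...) {
    validObject(params)
    g <- img@pixels
    if (params@noiseSigma == 0)
      return(rewrap(img, g, list(filterParams = params)))
    if (nrow(g) < params@searchWindow + params@blockSize ||
        ncol(g) < params@searchWindow + params@blockSize)
      stop("image must be larger than blockSize + searchWindow")
    zero <- matrix(0, 1, 1)
    stage1 <- .cpp_bm3d_stage(g, g, zero, params@noiseSigma, params@gamma,
                              params@blockSize, params@maxGroup,
                              params@lambdaThr, params@mu,
                              params@searchWindow, params@step, FALSE)
    stage2 <- .cpp_bm3d_stage(g, stage1, stage1, params@noiseSigma, 0,
                              params@blockSize, params@maxGroup,
                              params@lambdaThr, params@mu,
                              params@searchWindow, params@step, TRUE)
    rewrap(img, pmax(stage2, 0),
           list(filterParams = params, bm3dStage1 = pmax(stage1, 0)))
  })

#' Trimmed mean of one window
#'
#' Sorts the window ascending, zero-weights `ceiling(alpha * n)` entries at
#' each end and averages the survivors. `alpha = 0` is the plain mean; as
#' `alpha` approaches 0.5 the filter turns into a median (when trimming
#' removes every element, the median element is returned). A 1e-9 guard
#' keeps `ceiling` from overshooting on exact-integer products.
#'
#' @param values numeric vector of window intensities (length M^2 for an
#'   M x M window, M odd).
#' @param alpha trimming fraction between 0 and 0.5.
#' @return the trimmed mean.
#' @examples
#' trimmedMean(1:9, 0)                      # plain mean
#' trimmedMean(c(1:8, 100), 0.12)           # 2 trimmed per end
#' trimmedMean(1:9, 0.5)                    # median
#' @export
trimmedMean <- function(values, alpha) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            alpha >= 0, alpha <= 0.5)
  v <- sort(values)
  n <- length(v)
  t <- ceiling(alpha * n - 1e-9)
  if (n - 2 * t <= 0) {
    if (n %% 2L == 1L) v[(n + 1L) / 2L]
    else mean(v[c(n / 2L, n / 2L + 1L)])
  } else {
    mean(v[(t + 1L):(n - t)])
  }
}

#' Adaptive alpha-trimmed mean filter
#'
#' Per pixel, the window size shrinks and the trimming fraction grows with
#' the pixel intensity relative to the image maximum, so photon-starved
#' regions get aggressive box averaging while bright regions approach median
#' filtering over small windows (preserving resolution). Signal below
#' `delta` always receives the maximum window `beta`. The real-valued window
#' size is rounded to the nearest odd integer (ties upward) and clipped to
#' `[3, beta]`. An all-zero image is returned unchanged.
#'
#' @rdname denoise
#' @export
setMethod("denoise", signature("CherenkovImage", "ATMParams"),
  function(img, params, ...) {
    validObject(params)
    out <- .cpp_atm(img@pixels, params@beta, params@lambda, params@delta)
    rewrap(img, out, list(filterParams = params))
  })

#' Bilateral filter
#'
#' Gaussian-weighted mean combining geometric closeness (`sigmaS`, pixels)
#' and intensity similarity (`sigmaR`, counts) over a square support window,
#' normalized by the total weight. As `sigmaR` grows the range kernel tends
#' to 1 and the filter reduces to plain Gaussian smoothing.
#'
#' @rdname denoise
#' @export
setMethod("denoise", signature("CherenkovImage", "BilateralParams"),
  function(img, params, ...) {
    validObject(params)
    out <- .cpp_bilateral(img@pixels, params@sigmaS, params@sigmaR,
                          params@window)
    rewrap(img, out, list(filterParams = params))
  })
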