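#' @include accessors.R params.R filters.R metrics-psnr.R
NULL

#' The published sweep ranges for each filter
#'
#' Emits the study's parameter ranges discretized at `nPoints` values per
#' axis: TV-L1 lambda over 0.01 to 3.5 (log-spaced, the range spans
#' decades), NLM sigma over (0, 7000), BM3D sigma over (0, 10000] (both
#' linear; the zero endpoint is replaced by the smallest positive grid value
#' since the weight formulas divide by sigma^2), ATM lambda over 2 to 14,
#' and for the bilateral filter sigma_s over 1 to 18 crossed with the range
#' degree-of-smoothing sigma_r^2 over 100 v to 11000 v (log-spaced), where
#' `v` is the variance of a background patch. The range axis multiplies a
#' variance, so its values are the range-kernel variance; the filter's
#' sigma_r is their square root.
#'
#' @param filterId one of "tvl1", "nlm", "bm3d", "atm", "bilateral".
#' @param backgroundVariance background-patch variance v (counts^2);
#'   required (> 0) for the bilateral grid.
#' @param nPoints grid density per axis for the 1D sweeps (default 15).
#' @param nPointsBilateral per-axis density of the bilateral 2D grid
#'   (default 10).
#' @return a [SweepGrid-class].
#' @export
defaultGrid <- function(filterId, backgroundVariance = NULL, nPoints = 15L,
                        nPointsBilateral = 10L) {
  n <- as.integer(nPoints)
  switch(filterId,
    tvl1 = new("SweepGrid", filterId = "tvl1",
               axes = list(lambda = exp(seq(log(0.01), log(3.5),
                                            length.out = n))),
               fixed = list(nIter = 100L)),
    nlm = new("SweepGrid", filterId = "nlm",
              axes = list(sigma = seq(0, 7000, length.out = n + 1L)[-1]),
              fixed = list()),
    bm3d = new("SweepGrid", filterId = "bm3d",
               axes = list(noiseSigma = seq(0, 10000,
                                            length.out = n + 1L)[-1]),
               fixed = list()),
    atm = new("SweepGrid", filterId = "atm",
              axes = list(lambda = seq(2, 14, length.out = n)),
              fixed = list()),
    bilateral = {
      if (is.null(backgroundVariance) || backgroundVariance <= 0)
        stop("bilateral grid needs backgroundVariance > 0")
      nb <- as.integer(nPointsBilateral)
      # the published range axis multiplies a background *variance*, i.e. it
      # sweeps the range-kernel variance (a degree of smoothing, counts^2);
      # the filter's sigma_r (counts) is its square root
      new("SweepGrid", filterId = "bilateral",
          axes = list(
            sigmaS = seq(1, 18, length.out = nb),
            sigmaR2 = exp(seq(log(100 * backgroundVariance),
                              log(11000 * backgroundVariance),
                              length.out = nb))),
          fixed = list())
    },
    stop("unknown filterId: ", filterId))
}

# preference order for tie-breaking: least aggressive parameter first
# (largest TV/ATM lambda, smallest NLM/BM3D sigma, smallest bilateral sigmas)
preference_order <- function(filter_id, grid_df) {
  switch(filter_id,
    tvl1 = order(-grid_df$lambda),
    atm = order(-grid_df$lambda),
    nlm = order(grid_df$sigma),
    bm3d = order(grid_df$noiseSigma),
    bilateral = order(grid_df$sigmaS, grid_df$sigmaR2))
}

#' Sweep a filter's parameter grid for maximal PSNR
#'
#' Evaluates the filter at every grid point, scores each denoised image by
#' PSNR against the ground truth and returns the full trace with the argmax.
#' Deterministic given its inputs. Exact PSNR ties break toward the least
#' aggressive parameter (largest TV-L1/ATM lambda, smallest NLM/BM3D sigma,
#' smallest bilateral scales). A filter failure at a grid point is recorded
#' as `NA` and excluded from the argmax; an argmax on a grid boundary
#' triggers a warning suggesting the grid be extended.
#'
#' @param truth,noisy aligned ground-truth and noisy images.
#' @param grid a [SweepGrid-class].
#' @param verbose print per-point progress.
#' @return a [SweepResult-class].
#' @export
sweepFilter <- function(truth, noisy, grid, verbose = FALSE) {
  stopifnot(is(grid, "SweepGrid"))
  validObject(grid)
  pts <- expand.grid(grid@axes, KEEP.OUT.ATTRS = FALSE)
  ps <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    params <- params_from_point(grid@filterId, pts[i, , drop = FALSE],
                                grid@fixed)
    res <- tryCatch(denoise(noisy, params), error = function(e) NULL)
    if (!is.null(res)) ps[i] <- psnr(truth, res)
    if (verbose)
      message(sprintf("  %s point %d/%d: PSNR %.3f", grid@filterId, i,
                      nrow(pts), ps[i]))
  }
  if (all(is.na(ps))) stop("every grid point failed for ", grid@filterId)
  best <- max(ps, na.rm = TRUE)
  pref <- preference_order(grid@filterId, pts)
  bestIdx <- pref[which(ps[pref] == best)[1]]
  bestPt <- pts[bestIdx, , drop = FALSE]
  boundary <- any(vapply(names(grid@axes), function(ax) {
    vals <- grid@axes[[ax]]
    length(vals) > 1L && bestPt[[ax]] %in% range(vals)
  }, logical(1)))
  if (boundary)
    warning(sprintf("sweep argmax for %s lies on a grid boundary; consider extending the grid",
                    grid@filterId))
  noisyPsnr <- psnr(truth, noisy)
  trace <- cbind(pts, psnr = ps)
  new("SweepResult", filterId = grid@filterId, trace = trace,
      bestParams = params_from_point(grid@filterId, bestPt, grid@fixed),
      bestPsnr = best, noisyPsnr = noisyPsnr,
      percentIncrease = 100 * (best - noisyPsnr) / noisyPsnr,
      boundary = boundary)
}

#' Largest inscribed background rectangle of a synthetic scene
#'
#' The zero-signal phantom margin of a generated scene serves as the
#' background patch whose variance calibrates the bilateral sigma_r range.
#' Returns the top margin band as `c(x, y, width, height)`.
#'
#' @param scene the [SceneSpec-class] that generated the image.
#' @return integer(4) ROI.
#' @export
backgroundRegion <- function(scene) {
  m <- scene@phantomMargin
  if (m < 2L) stop("scene has no usable zero-signal margin")
  c(1L, 1L, scene@width, m)
}
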