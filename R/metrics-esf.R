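#' @include accessors.R
NULL

#' Extract the edge spread function from a slanted-edge ROI
#'
#' Estimates the edge line by locating the 50%-crossing of each row and
#' fitting a straight line through the crossings, projects every ROI pixel
#' onto the edge-normal axis, and bins the projected intensities at
#' `oversampling` bins per pixel (4 by default, standard slanted-edge
#' practice). Positions are oriented so the profile rises from the dark to
#' the bright side.
#'
#' @param img a [CherenkovImage-class] or matrix.
#' @param roi integer(4) `c(x, y, width, height)`: 1-based column/row origin
#'   and extent of a region containing one near-vertical high-contrast edge.
#' @param oversampling bins per pixel.
#' @return an [ESFCurve-class]; the fitted edge angle (degrees from
#'   vertical) is in its `edgeAngle` slot.
#' @export
extractESF <- function(img, roi, oversampling = 4) {
  px <- as_pixels(img)
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > ncol(px) || y0 + h - 1 > nrow(px))
    stop("roi exceeds image bounds")
  Z <- px[y0:(y0 + h - 1), x0:(x0 + w - 1), drop = FALSE]
  nfl <- max(2L, floor(w * 0.2))
  cm <- colMeans(Z)
  leftBright <- mean(cm[seq_len(nfl)]) > mean(cm[(w - nfl + 1):w])
  glo <- min(mean(cm[seq_len(nfl)]), mean(cm[(w - nfl + 1):w]))
  ghi <- max(mean(cm[seq_len(nfl)]), mean(cm[(w - nfl + 1):w]))
  if (!(ghi - glo > 1e-9 * max(abs(Z), 1)))
    stop("no edge: ROI has no contrast")
  gmid <- (glo + ghi) / 2
  gcross <- which((cm[-w] - gmid) * (cm[-1] - gmid) <= 0)
  gcross <- if (length(gcross)) gcross[ceiling(length(gcross) / 2)] else w / 2
  crossings <- rep(NA_real_, h)
  for (r in seq_len(h)) {
    v <- Z[r, ]
    lo <- mean(v[seq_len(nfl)]); hi <- mean(v[(w - nfl + 1):w])
    mid <- (lo + hi) / 2
    idx <- which((v[-w] - mid) * (v[-1] - mid) <= 0 & v[-w] != v[-1])
    if (!length(idx)) next
    i <- idx[which.min(abs(idx - gcross))]
    crossings[r] <- i + (mid - v[i]) / (v[i + 1] - v[i])
  }
  ok <- is.finite(crossings)
  if (mean(ok) < 0.8)
    stop("no edge: monotone transition missing in > 20% of rows")
  fit <- lm(crossings[ok] ~ seq_len(h)[ok])
  a <- coef(fit)[1]; b <- coef(fit)[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist <- (cols - (a + b * rows)) / sqrt(1 + b^2)
  if (leftBright) dist <- -dist
  bin <- round(as.vector(dist) * oversampling)
  agg <- tapply(as.vector(Z), bin, mean)
  ks <- as.numeric(names(agg))
  o <- order(ks)
  new("ESFCurve", positions = ks[o] / oversampling,
      values = as.numeric(agg[o]), oversampling = oversampling,
      edgeAngle = atan(b) * 180 / pi)
}

#' Modulation transfer function from an edge spread function
#'
#' Differentiates the (uniformly resampled) ESF by forward finite
#' differences to the line spread function (a single-tap derivative, so a
#' perfect step transfers flatly; its sub-percent sinc attenuation is far
#' below the tolerances used here), applies a Hann window centered on the
#' LSF centroid to suppress tail noise, and takes the normalized FFT
#' magnitude. The frequency axis accounts for the sub-pixel oversampling and
#' is truncated at the Nyquist frequency of the original sampling
#' (0.5 cycles/pixel).
#'
#' @param esf an [ESFCurve-class] (should cover at least ~20 pixels on each
#'   side of the edge for stable tails).
#' @return an [MTFCurve-class].
#' @export
esfToMTF <- function(esf) {
  stopifnot(is(esf, "ESFCurve"))
  os <- esf@oversampling
  step <- 1 / os
  grid <- seq(min(esf@positions), max(esf@positions), by = step)
  v <- approx(esf@positions, esf@values, xout = grid, rule = 2)$y
  n <- length(v)
  if (n < 8L) stop("ESF support too short")
  lsf <- numeric(n)
  lsf[1:(n - 1)] <- (v[2:n] - v[1:(n - 1)]) / step
  wgt <- abs(lsf)
  if (sum(wgt) == 0) stop("zero LSF area")
  ctr <- sum(seq_len(n) * wgt) / sum(wgt)
  idx <- seq_len(n)
  han <- ifelse(abs(idx - ctr) <= n / 2,
                0.5 * (1 + cos(2 * pi * (idx - ctr) / n)), 0)
  spec <- Mod(fft(lsf * han))
  if (spec[1] == 0) stop("zero LSF area")
  freqs <- (idx - 1) / (n * step)
  keep <- freqs <= 0.5 + 1e-12
  new("MTFCurve", freqs = freqs[keep], values = spec[keep] / spec[1])
}

#' MTF50 and MTF10 summary frequencies
#'
#' The first crossings of the 50% and 10% modulation levels, linearly
#' interpolated between bracketing samples. A level never reached below
#' Nyquist is reported as `NA` (absent), not extrapolated.
#'
#' @param mtf an [MTFCurve-class].
#' @return list with numeric `mtf50` and `mtf10` (cycles/pixel, or `NA`).
#' @export
mtfSummary <- function(mtf) {
  stopifnot(is(mtf, "MTFCurve"))
  crossing <- function(level) {
    v <- mtf@values; f <- mtf@freqs
    i <- which(v[-length(v)] >= level & v[-1] < level)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    f[i] + (v[i] - level) / (v[i] - v[i + 1]) * (f[i + 1] - f[i])
  }
  list(mtf50 = crossing(0.5), mtf10 = crossing(0.1))
}

#' 10-90% rise distance of an edge
#'
#' Distance between the interpolated 10% and 90% crossings of the low-to-
#' high plateau span of the ESF; larger values mean a blurrier edge.
#'
#' @param esf an [ESFCurve-class] with identifiable plateaus.
#' @return rise distance in pixels.
#' @export
riseDistance <- function(esf) {
  stopifnot(is(esf, "ESFCurve"))
  v <- esf@values; p <- esf@positions
  n <- length(v)
  k <- max(3L, floor(n * 0.1))
  lo <- median(v[seq_len(k)])
  hi <- median(v[(n - k + 1):n])
  if (!(hi - lo > 1e-9 * max(abs(v), 1)))
    stop("plateaus not identifiable")
  l10 <- lo + 0.1 * (hi - lo)
  l90 <- lo + 0.9 * (hi - lo)
  i90 <- which(v >= l90)[1]
  if (is.na(i90) || i90 < 2L) stop("plateaus not identifiable")
  below <- which(v[seq_len(i90 - 1L)] <= l10)
  if (!length(below)) stop("plateaus not identifiable")
  i10 <- max(below)
  interp <- function(i, level) {
    j <- i
    while (j < n && v[j + 1] == v[j]) j <- j + 1
    p[j] + (level - v[j]) / (v[j + 1] - v[j]) * (p[j + 1] - p[j])
  }
  x10 <- interp(i10, l10)
  j90 <- i90 - 1L
  x90 <- p[j90] + (l90 - v[j90]) / (v[i90] - v[j90]) * (p[i90] - p[j90])
  abs(x90 - x10)
}
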