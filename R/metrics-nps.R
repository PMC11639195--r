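#' @include accessors.R
NULL

#' Noise power spectrum (2D and radially averaged)
#'
#' Tiles the analysis region with overlapping square ROIs, subtracts each
#' ROI's mean (first-order detrend; the synthetic plateaus are flat), and
#' averages the squared 2D FFT magnitudes scaled by `dx * dy / N^2`, giving
#' a spectrum in counts^2 mm^2. Each ROI's 2D spectrum is also radially
#' binned about zero frequency (bin width of one frequency-sample spacing,
#' `1 / (N * dx)`); the radial curve is the per-bin mean over ROIs, with the
#' per-bin standard deviation across ROIs as its error estimate. Bins
#' holding no samples are dropped.
#'
#' @param img a [CherenkovImage-class] (the pitch supplies dx, dy) or a
#'   matrix (pitch 0.5 mm assumed).
#' @param roiSize ROI side N in pixels (default 100).
#' @param overlapFraction fractional overlap of adjacent ROIs in both axes
#'   (default 0.5, chosen by the geometric restrictions of the image).
#' @param region optional `c(x, y, width, height)` sub-rectangle to analyze.
#' @return an [NPSResult-class].
#' @export
computeNPS <- function(img, roiSize = 100L, overlapFraction = 0.5,
                       region = NULL) {
  px <- as_pixels(img)
  pitch <- if (is(img, "CherenkovImage")) img@pixelPitch else c(0.5, 0.5)
  if (!is.null(region)) {
    px <- px[region[2]:(region[2] + region[4] - 1),
             region[1]:(region[1] + region[3] - 1), drop = FALSE]
  }
  N <- as.integer(roiSize)
  if (nrow(px) < N || ncol(px) < N)
    stop("analysis region smaller than roiSize in at least one axis")
  stride <- max(1L, as.integer(round(N * (1 - overlapFraction))))
  starts <- function(extent) {
    s <- seq(1L, extent - N + 1L, by = stride)
    if (s[length(s)] != extent - N + 1L) s <- c(s, extent - N + 1L)
    s
  }
  ri <- starts(nrow(px)); rj <- starts(ncol(px))
  M <- length(ri) * length(rj)
  if (M < 2L) stop("fewer than 2 ROIs fit the analysis region")
  dx <- pitch[2]; dy <- pitch[1]
  scale <- dx * dy / N^2
  # radial binning geometry (shared across ROIs)
  k <- seq_len(N) - 1L
  k <- ifelse(k >= N / 2, k - N, k)  # unshifted FFT order
  fx <- outer(rep(1, N), k / (N * dx))
  fy <- outer(k / (N * dy), rep(1, N))
  rad <- sqrt(fx^2 + fy^2)
  db <- 1 / (N * dx)
  binIdx <- as.integer(round(rad / db))
  bins <- sort(unique(as.vector(binIdx)))
  counts <- as.vector(table(factor(as.vector(binIdx), levels = bins)))
  binFac <- factor(as.vector(binIdx), levels = bins)
  nps2d <- matrix(0, N, N)
  profiles <- matrix(NA_real_, M, length(bins))
  m <- 0L
  for (i in ri) for (j in rj) {
    m <- m + 1L
    z <- px[i:(i + N - 1L), j:(j + N - 1L)]
    z <- z - mean(z)
    p2 <- Mod(fft(z))^2 * scale
    nps2d <- nps2d + p2
    profiles[m, ] <- rowsum(as.vector(p2), binFac) / counts
  }
  nps2d <- nps2d / M
  shift <- function(mat) {
    h <- N %/% 2
    mat[c((h + 1):N, 1:h), c((h + 1):N, 1:h)]
  }
  new("NPSResult", nps2d = shift(nps2d), radialFreqs = bins * db,
      radialValues = colMeans(profiles),
      radialStd = apply(profiles, 2, sd),
      binCounts = counts, roiSize = N, nRois = as.integer(M),
      pixelPitch = pitch)
}
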