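---
title: "Denoising cumulative Cherenkov images: models, metrics and design notes"
author: "CherenkovDenoise authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising cumulative Cherenkov images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CherenkovDenoise)
```

## The problem

Cherenkov imaging during external-beam radiotherapy records the faint
visible light emitted where accelerated electrons outrun the local speed of
light in tissue; the cumulative (frame-summed) image serves as a surrogate
map of surface dose. Very few photons reach the time-gated camera per frame,
so even after summing thousands of frames the image retains photon shot
noise, sensor read noise, sporadic stray-radiation impulses, and the
low-frequency mottle left behind by the camera's own temporal/spatial median
preprocessing. This package implements a complete, reproducible pipeline for
studying classical denoisers on such data: a synthetic acquisition model, the
five filters, image-quality metrics, PSNR-driven parameter optimization and a
benchmark with comparison statistics.

## The synthetic acquisition model

Real acquisitions of this kind are rarely shareable, so the generator
(`makeTruthScene()`, `simulateCumulative()`, `makeDataset()`) emulates the
statistical structure the analysis relies on.

**Scene.** The noiseless per-frame expectation is a smooth beam plateau with
Gaussian vignette falloff, zero outside a phantom margin, and zero on the
occluded side of a slanted edge 2-12 degrees from vertical — the
high-contrast feature every slanted-edge sharpness method assumes.

**Per-frame noise.** Each frame draws Poisson counts at the expectation plus
a constant ambient background, adds Gaussian read noise, and with small
probability injects a uniform-amplitude impulse (stray x-ray photons;
amplitudes are nonnegative, so an impulse never lowers a raw value). The
camera preprocessing follows: a centered rolling temporal median across
frames (truncated at the sequence edges rather than fabricating frames), a
per-frame spatial median, and subtraction of the *configured* background
expectation — estimating the background per frame would make the generator
non-analytic and is out of scope. Frames are summed and clipped at zero.

**MU scaling.** Noise level is controlled by the frame count, proportional
to delivered monitor units. The noisy accumulation is rescaled by
`framesTruth / framesNoisy` so both images share one intensity scale. The
ground truth defaults to the analytic expectation times `framesTruth`
(flagged in metadata); a fully simulated truth is available for tests.

**Chosen conditions.** No public number fixes the per-frame intensity,
median windows, background level or object-plane pixel pitch, so the
defaults were set once to values a low-light radiotherapy camera plausibly
produces, and on which the published *absolute* parameter ranges of the
denoisers (an NLM aggressiveness up to 7000 counts, a BM3D noise std up to
10 000 counts, an ATM low-signal cutoff of 5 counts) are meaningful:

* plateau 2.2 photons/pixel/frame, so the 9000-frame truth plateau is
  about 2e4 summed counts;
* background 0.15 counts/pixel/frame, read noise 0.6 counts;
* impulses at rate 2e-4/pixel/frame with amplitudes U[50, 200] — bright
  enough to saturate locally relative to the per-frame signal, mostly (but
  not entirely) removed by the temporal median;
* temporal median over 3 frames, spatial median 3 x 3;
* pixel pitch 0.5 mm/pixel in the object plane (configurable; every NPS
  result records the pitch it used).

The per-frame RNG substreams are split by counter from the dataset seed, so
changing the frame count never reshuffles earlier frames; identical seeds
give bit-identical datasets.

**What the generator does not emulate.** Lens point-spread and perspective,
time-gating electronics, patient motion, skin-tone-dependent attenuation,
and any spatial correlation in the ambient background. Consequently, a
filter ranking measured here shows how the methods respond to
median-filtered counting noise around a high-contrast field edge — not how
they respond to every feature of clinical data.

## The five filters

All filters are pure operations on a `CherenkovImage`, preserve shape and
pixel pitch, use half-sample symmetric (mirror) boundary padding (avoiding
the zero-padding bias a windowed filter would otherwise inject into plateau
statistics), and record their parameters in the result metadata.

**TV-L1** (`tvParams()`): minimizes `||grad I||_2 + lambda ||I - G||_1` by a
primal-dual saddle-point scheme, isotropic forward-difference gradient with
Neumann boundary, primal step 0.25 and dual step 0.125 (the standard stable
pair for that operator's norm). Two numerical choices matter. First, the
iteration runs on the max-normalized image: both objective terms are
1-homogeneous, so the minimizer is scale covariant with the *same* lambda,
while the fixed step sizes are sized for unit-scale data — on raw count
images the iteration would crawl. Second, the plain saddle-point iteration
does not guarantee a monotone primal cost, so the filter tracks the
best-cost iterate (the dual and extrapolation sequences advance on the raw
iterates) and returns it; the logged cost trace is therefore non-increasing
by construction, in the spirit of monotone FISTA variants. `nIter = 0`
returns the input unchanged; `lambda = 1e6` reproduces the input exactly
(the fidelity prox dominates).

**Non-local means** (`nlmParams()`): the integral-image formulation — for
each shift within the search window, a summed-squared-difference plane gives
every site's patch distance in O(1), the weight plane is
`exp(-ssd / sigma^2)`, and the shifted image accumulates into a normalized
weighted average. The conventional "20 x 20 window, 4 x 4 patch" sizes are
even; they are interpreted as centered half-sizes (10 and 2), giving
effective odd supports of 21 and 5 pixels. The patch kernel is uniform,
matching the integral-image formulation; a Gaussian-weighted variant exists
only inside the brute-force oracle `nlmDenoiseBrute()` behind a flag. The
self-shift enters with weight one — silently excluding it would change
results. The patch distance is divided by `sigma^2` without window-size
normalization, so `sigma` lives on the intensity scale and effectively
absorbs the patch area. `denoise()` (fast path) and `nlmDenoiseBrute()`
agree to machine precision; the test suite holds them to 1e-8 of the
dynamic range on random images.

**BM3D** (`bm3dParams()`): two stages. Stage 1 matches, for each reference
block, the most similar blocks in a search neighborhood (the matching
distance subtracts `2 gamma N sigma^2`, the noise-bias term, with gamma = 3),
applies a separable 3D transform — 2D orthonormal DCT per block, 1D
orthonormal Haar across the group (group size truncated to a power of two) —
hard-thresholds at `lambdaThr * sigma`, inverts, and aggregates block
estimates weighted by `1 / (sigma^2 N_retained)`. Stage 2 re-matches on the
stage-1 estimate (gamma = 0) and replaces the threshold with empirical
Wiener gains `Y^2 / (Y^2 + mu^2 sigma^2)` driven by the stage-1
coefficients, aggregating with `1 / (sigma^2 sum g^2)`. Under the assumed
white-Gaussian noise PSD and orthonormal transforms the per-coefficient
variance collapses to `sigma^2`; a general PSD path is an extension point.
The transform pair, block size 8, group limit 16, threshold multiplier 2.7,
Wiener regularizer 1 and 39-pixel search window are the standard published
defaults of the reference method. Note the Wiener stage shrinks the group DC
by `(mu sigma / DC)^2`, so a constant image is a fixed point only up to that
quadratically small term (exactly, at `sigma = 0`).

**Adaptive alpha-trimmed mean** (`atmParams()`): per pixel, a window size
`M(x) = 2 beta lambda Max / (2 lambda Max + beta max(x - delta, 0))` and a
trimming fraction `alpha(x) = x / (lambda Max)` adapt to the pixel intensity
relative to the image maximum: photon-starved pixels get the largest window
(`beta`, default 31) with little trimming, bright pixels approach median
filtering over small windows. `lambda >= 2` keeps `alpha <= 0.5`. The
real-valued window size is rounded to the nearest odd integer (ties upward)
and clipped to `[3, beta]`; the trim count is the ceiling of `alpha M^2`,
computed with a 1e-9 guard so exact-integer products do not overshoot, and
when trimming removes every element the median element is returned (the
`alpha -> 0.5` contract). An all-zero image passes through unchanged.

**Bilateral** (`bilateralParams()`): Gaussian-weighted mean combining
geometric closeness (`sigmaS`, pixels) and intensity similarity (`sigmaR`,
counts) over a support window defaulting to `2 ceiling(2 sigmaS) + 1`. As
`sigmaR` grows the filter reduces to plain Gaussian smoothing. One subtlety
propagates into the sweep: the published range-parameter sweep multiplies a
background-patch *variance* by 100 to 11 000, i.e. it sweeps the
range-kernel variance (a degree of smoothing, counts^2) as MATLAB-style
bilateral implementations do; `defaultGrid("bilateral", ...)` therefore
carries a `sigmaR2` axis spanning `[100 v, 11000 v]` and the filter receives
`sigmaR = sqrt(value)`.

## Metrics

**PSNR** (`psnr()`): `20 log10(max(truth) / RMSE)` over all pixels. The
peak is the ground-truth maximum by the formula's reading; a data-type peak
can be substituted explicitly (`peak = "value"`), and the two differ.
Identical images return the `+Inf` sentinel.

**Slanted-edge sharpness** (`extractESF()`, `esfToMTF()`, `mtfSummary()`,
`riseDistance()`): each ROI row's 50%-crossing is located by linear
interpolation, a line is fitted through the crossings (its slope is the
reported edge angle), all ROI pixels are projected onto the edge normal and
binned at 4 bins/pixel — the standard oversampling for slanted-edge work.
An error is raised when more than 20% of rows lack a transition or the ROI
has no contrast. The LSF is the forward finite difference of the uniformly
resampled ESF: a single-tap derivative whose response is flat for a perfect
step and attenuates the measured band by well under 1%, unlike a centered
two-tap difference which already loses ~2% at a quarter-cycle. A Hann
window centered on the LSF centroid (keeping the pipeline
translation invariant) suppresses tail noise before the FFT; the magnitude
is normalized at zero frequency and truncated at the original Nyquist
frequency, 0.5 cycles/pixel. MTF50/MTF10 are first crossings by linear
interpolation, reported absent (`NA`) rather than extrapolated. The 10-90
rise distance interpolates the crossings of the low/high plateau span
(plateaus estimated from the outer 10% of bins).

**Noise power spectrum** (`computeNPS()`): overlapping square ROIs (default
side 100 pixels, 50% overlap — the overlap is whatever the image geometry
permits), per-ROI mean subtraction (a first-order detrend; the synthetic
plateaus are flat, and a polynomial detrend for sloped real data is a
straightforward extension), squared 2D FFT magnitudes scaled by
`dx dy / N^2`, averaged over ROIs. Radial profiles use bins one
frequency-sample wide, `1/(N dx)`; empty bins are dropped; the radial curve
is the per-bin mean across ROIs with the across-ROI standard deviation as
its error estimate. White noise of std sigma calibrates to
`sigma^2 dx dy` and the radial binning conserves total power exactly over
the stored bins. All mm^-1 axes are conditional on the configured pixel
pitch.

## Parameter sweeps and the benchmark

`sweepFilter()` evaluates a filter over `defaultGrid()`'s published ranges —
TV-L1 lambda in [0.01, 3.5] (log-spaced; the range spans decades), NLM sigma
in (0, 7000] and BM3D sigma in (0, 10000] (linear; the zero endpoint is
replaced by the smallest positive value because both weight formulas divide
by sigma^2), ATM lambda in [2, 14], bilateral sigmaS in [1, 18] crossed with
the range variance in [100 v, 11000 v] — scores each point by PSNR against
the truth, and returns the full trace plus the argmax. Exact ties break
toward the least aggressive parameter; a boundary argmax triggers a warning
to extend the grid. Failures at single grid points are recorded as `NA`,
not fatal. Joint multidimensional optimization beyond the bilateral's 2D
grid is deliberately not attempted.

`runBenchmark()` orchestrates the study: five 256 x 256 scenes varying edge
tilt, position, plateau level and vignette scale; 25 (and optionally 50)
MU-equivalent noise levels; all five filters with reduced default grids (7
points per 1D axis, 5 x 5 bilateral) so a full run stays in the minutes
range on one core; slanted-edge metrics from the scene's edge region
(images whose edge ROI fails the detection precondition are excluded from
sharpness statistics); NPS from the flat plateau with 64-pixel ROIs (the
256-pixel scenes cannot host 100-pixel ROIs), summarized as the mean over
0-1.5 mm^-1, the band most relevant to perception; and, per MU level, a
one-way ANOVA and Tukey HSD (95% family-wise level) across filters on the
percent PSNR increases. Everything is deterministic given the master seed,
and per-cell failures surface as `NA` rows.

## Known limitations and observed behavior

* The adaptive trimmed mean assigns its largest windows to photon-starved
  pixels by design; around the synthetic scene's high-contrast occluder and
  margin boundaries those windows average the bright plateau into the dark
  side. On these scenes the damage outweighs the plateau smoothing at every
  swept lambda, so ATM lands *below* the noisy baseline — the same failure
  direction the original formulation shows on one of its study images, and
  consistent with ATM's reputation for edge blurring. The benchmark reports
  it honestly rather than hiding the row.
* BM3D's white-noise PSD assumption does not match the median-filtered,
  spatially correlated residual noise, which caps its gains here.
* The TV-L1 cost safeguard makes the logged objective monotone but the
  returned iterate may differ from the raw final iterate on
  slowly-converging problems; increase `nIter` when chasing the exact
  minimizer.
* Sharpness tolerances assume the edge angle invariant (2-12 degrees from
  vertical) holds; nearly vertical or strongly tilted edges violate the
  projection geometry.

## What the tests demonstrate

The suite pins each operation to an independent oracle: literal per-pixel
re-evaluations (NLM, ATM), closed forms (Gaussian-edge MTF50/MTF10 and
rise distance, white-noise NPS level, PSNR identities), exhaustive search
(a tiny TV-L1 instance), textbook transforms (DCT/Haar), permutation
resampling (ANOVA), and the studentized-range formula (Tukey). Passing
them shows the implementations compute what their formulas say on data with
the generator's statistical structure; it does not certify performance on
clinical Cherenkov images, which add optics, motion and background features
the generator deliberately omits.
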