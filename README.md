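# CherenkovDenoise

Noise and mottle suppression for cumulative Cherenkov images of radiation
therapy delivery, with the quality metrics and statistics needed to compare
denoisers fairly.

Cherenkov cameras image the faint visible light emitted where a linac beam
deposits dose near the skin, giving a surrogate map of surface dose. Very
few photons arrive per frame; even the cumulative image (thousands of
summed, time-gated frames) keeps shot noise, read noise, stray x-ray
impulses and low-frequency mottle. This package is for medical-physics and
image-analysis researchers who want to benchmark classical denoisers on
that regime — including when the original camera data cannot be shared, via
a synthetic acquisition model with the same statistical structure.

## What it provides

* **Synthetic acquisition** — `makeTruthScene()`, `simulateCumulative()`,
  `makeDataset()`: a beam plateau with vignette falloff and a slanted
  occluder edge; per-frame Poisson shot noise + Gaussian read noise +
  impulses; camera-side temporal/spatial median filtering and background
  subtraction; frame summation scaled to monitor units (MU), so 25 MU- and
  50 MU-equivalent noisy images pair with a 9000-frame ground truth.
* **Five denoisers** behind one generic, `denoise(img, params)`:
  - TV-L1, `arg min ||∇I||₂ + λ||I − G||₁`, primal-dual iteration
    (`tvParams`);
  - fast non-local means via integral images of squared differences, with
    weights `exp(−S_d/σ²)` (`nlmParams`; brute-force oracle
    `nlmDenoiseBrute`);
  - two-stage BM3D: block matching, 2D DCT + 1D Haar group transform, hard
    threshold `λσ`, then Wiener shrinkage `Y²/(Y² + μ²σ²)` (`bm3dParams`);
  - 2D adaptive alpha-trimmed mean with intensity-adaptive window
    `M(x)` and trim fraction `α(x) = x/(λ·Max)` (`atmParams`,
    `trimmedMean`);
  - bilateral filter with Gaussian domain and range kernels
    (`bilateralParams`).
* **Metrics** — `psnr()` (`20·log₁₀(max(x)/RMSE)`); slanted-edge sharpness
  `extractESF()` → `esfToMTF()` → `mtfSummary()` (MTF50/MTF10) and
  `riseDistance()` (10–90%); radially averaged noise power spectrum
  `computeNPS()` per `NPS(νx,νy) = ΔxΔy/(MN²) Σ|FFT(ROI − mean)|²`.
* **Optimization and comparison** — `defaultGrid()` reproduces the
  published sweep ranges, `sweepFilter()` picks the PSNR-maximizing
  parameters, `runBenchmark()` runs the full study and `oneWayAnova()` /
  `tukeyHsd()` compare the per-filter percent PSNR gains.

## Worked example

```r
library(CherenkovDenoise)

scene <- sceneSpec(height = 128L, width = 128L)
acq   <- acquisitionSpec(framesNoisy = 25L, seed = 7L)   # 25 MU-equivalent
ds    <- makeDataset(scene, acq, noiseModel())
cat(sprintf("noisy PSNR: %.2f dB\n", psnr(ds$truth, ds$noisy)))

grid <- defaultGrid("tvl1", nPoints = 7L)
res  <- sweepFilter(ds$truth, ds$noisy, grid)
show(res)

den <- denoise(ds$noisy, res@bestParams)
esf <- extractESF(den, edgeRegion(scene))
s   <- mtfSummary(esfToMTF(esf))
cat(sprintf("edge angle %.1f deg, MTF50 %.3f cy/px, 10-90 rise %.1f px\n",
            esf@edgeAngle, s$mtf50, riseDistance(esf)))
```

prints

```
noisy PSNR: 22.09 dB
SweepResult [tvl1]: 7 grid points
  noisy PSNR 22.09 dB -> best 22.63 dB (+2.41%)
edge angle 5.0 deg, MTF50 0.280 cy/px, 10-90 rise 2.0 px
```

The sweep found the TV-L1 regularization (λ ≈ 0.5, inside the published
optimum band) that raises PSNR by 2.4% on this 128-pixel scene; the
slanted-edge analysis recovered the 5° occluder tilt and reports the
denoised edge's MTF50 in cycles/pixel and its 10–90% rise distance in
pixels (larger rise = blurrier).

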