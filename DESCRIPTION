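Package: CherenkovDenoise
Title: Denoising and Image-Quality Benchmarking for Cumulative Cherenkov
    Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for suppressing noise and mottle in cumulative Cherenkov
    images of radiotherapy delivery. Provides a synthetic acquisition model
    (per-frame Poisson shot noise, Gaussian read noise, stray-radiation
    impulses, camera-side temporal and spatial median filtering, frame
    summation scaled to linac monitor units), five denoising filters
    (TV-L1 primal-dual minimization, fast non-local means with integral
    images, two-stage BM3D collaborative filtering, a 2D adaptive
    alpha-trimmed mean, and bilateral filtering), image-quality metrics
    (PSNR, slanted-edge ESF/LSF/MTF sharpness, radially averaged noise
    power spectra), PSNR-driven parameter sweeps, and a benchmark
    orchestrator with one-way ANOVA and Tukey HSD comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'CherenkovDenoise-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'metrics-nps.R'
    'metrics-esf.R'
    'params.R'
    'synthetic.R'
    'stats.R'
    'metrics-psnr.R'
    'filters.R'
    'sweep.R'
    'benchmark.R'
    'io.R'
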