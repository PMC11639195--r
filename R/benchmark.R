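#' @include sweep.R stats.R synthetic.R metrics-esf.R metrics-nps.R
NULL

#' Construct a BenchmarkConfig
#'
#' Defaults describe the desk-scale study: five 256 x 256 scenes, the
#' default camera noise model, 25 and 50 MU-equivalent noise levels, all
#' five filters with reduced sweep grids (7 points per 1D axis, 5 x 5 for
#' the bilateral), and a 64-pixel NPS ROI (the plateau region of a 256-pixel
#' scene does not fit 100-pixel ROIs).
#'
#' @param scenes list of [SceneSpec-class] objects.
#' @param noise shared [NoiseModel-class].
#' @param muLevels MU-equivalent levels at which images are generated and
#'   filters swept.
#' @param filters filter ids to benchmark.
#' @param gridPoints 1D sweep density per axis.
#' @param bilateralGridPoints per-axis density of the bilateral 2D sweep.
#' @param npsRoiSize ROI side for per-image NPS curves.
#' @param framesTruth ground-truth accumulation frames.
#' @param muPerFrame MU per frame.
#' @param masterSeed integer; scene i draws from seed `masterSeed + i`.
#' @param withStats compute ANOVA/Tukey across filters per MU level.
#' @param outDir optional directory for CSV/JSON artifacts ("" disables).
#' @return a [BenchmarkConfig-class].
#' @export
benchmarkConfig <- function(scenes = defaultScenes(), noise = noiseModel(),
                            muLevels = c(25, 50),
                            filters = c("tvl1", "nlm", "bm3d", "atm",
                                        "bilateral"),
                            gridPoints = 7L, bilateralGridPoints = 5L,
                            npsRoiSize = 64L, framesTruth = 9000L,
                            muPerFrame = 1, masterSeed = 1L,
                            withStats = length(scenes) >= 2L, outDir = "")
  new("BenchmarkConfig", scenes = scenes, noise = noise,
      muLevels = as.numeric(muLevels), filters = filters,
      gridPoints = as.integer(gridPoints),
      bilateralGridPoints = as.integer(bilateralGridPoints),
      npsRoiSize = as.integer(npsRoiSize),
      framesTruth = as.integer(framesTruth),
      muPerFrame = as.numeric(muPerFrame),
      masterSeed = as.integer(masterSeed), withStats = isTRUE(withStats),
      outDir = outDir)

#' Slanted-edge analysis region of a synthetic scene
#'
#' A rectangle straddling the occluder edge at mid-height, sized so the
#' tilted edge stays inside it.
#'
#' @param scene a [SceneSpec-class].
#' @param halfWidth,halfHeight half-extents in pixels.
#' @return integer(4) `c(x, y, width, height)`.
#' @export
edgeRegion <- function(scene, halfWidth = 24L, halfHeight = 48L) {
  xc <- round(scene@edgePosition * scene@width)
  yc <- round((scene@height + 1) / 2)
  x0 <- max(1L, xc - halfWidth); x1 <- min(scene@width, xc + halfWidth)
  y0 <- max(1L, yc - halfHeight); y1 <- min(scene@height, yc + halfHeight)
  c(x0, y0, x1 - x0 + 1L, y1 - y0 + 1L)
}

#' Flat plateau region of a synthetic scene (for NPS)
#'
#' The unoccluded beam plateau left of the slanted edge, inset from the
#' phantom margin and the edge sweep band.
#'
#' @param scene a [SceneSpec-class].
#' @param inset pixels of clearance from margin and edge.
#' @return integer(4) `c(x, y, width, height)`.
#' @export
plateauRegion <- function(scene, inset = 6L) {
  m <- scene@phantomMargin
  slope <- tan(scene@edgeAngle * pi / 180)
  xEdgeMin <- scene@edgePosition * scene@width -
    abs(slope) * scene@height / 2
  x0 <- m + inset + 1L
  x1 <- as.integer(floor(xEdgeMin)) - inset
  y0 <- m + inset + 1L
  y1 <- scene@height - m - inset
  if (x1 <= x0 || y1 <= y0) stop("scene has no usable plateau region")
  c(as.integer(x0), as.integer(y0), as.integer(x1 - x0 + 1L),
    as.integer(y1 - y0 + 1L))
}

sharpness_row <- function(img, roi) {
  out <- list(mtf50 = NA_real_, mtf10 = NA_real_, rise1090 = NA_real_)
  esf <- tryCatch(extractESF(img, roi), error = function(e) NULL)
  if (is.null(esf)) return(out)
  mtf <- tryCatch(esfToMTF(esf), error = function(e) NULL)
  if (!is.null(mtf)) {
    s <- mtfSummary(mtf)
    out$mtf50 <- s$mtf50; out$mtf10 <- s$mtf10
  }
  out$rise1090 <- tryCatch(riseDistance(esf), error = function(e) NA_real_)
  out
}

nps_band_mean <- function(npsRes, band = 1.5) {
  if (is.null(npsRes)) return(NA_real_)
  keep <- npsRes@radialFreqs <= band
  mean(npsRes@radialValues[keep])
}

#' Run the full denoising benchmark
#'
#' For each scene and MU level: generates the truth/noisy pair, sweeps every
#' configured filter for maximal PSNR, computes PSNR, slanted-edge sharpness
#' (MTF50/MTF10, 10-90 rise) and the radially averaged NPS (summarized as
#' the mean over 0-1.5 mm^-1, the band most visible to the eye) for the
#' noisy image and each swept-optimal denoised image, then compares the
#' per-filter percent PSNR increases by one-way ANOVA and Tukey HSD per MU
#' level. Deterministic given the master seed. Failures are isolated per
#' (image, filter) cell and surface as `NA` rows, not errors.
#'
#' @param cfg a [BenchmarkConfig-class].
#' @param verbose print per-stage progress to stderr.
#' @return a [BenchmarkReport-class].
#' @export
runBenchmark <- function(cfg, verbose = FALSE) {
  stopifnot(is(cfg, "BenchmarkConfig"))
  validObject(cfg)
  rows <- list(); sweeps <- list(); npsList <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (i in seq_along(cfg@scenes)) {
    scene <- cfg@scenes[[i]]
    eroi <- edgeRegion(scene)
    proi <- tryCatch(plateauRegion(scene), error = function(e) NULL)
    for (mu in cfg@muLevels) {
      frames <- max(1L, as.integer(round(mu / cfg@muPerFrame)))
      acq <- acquisitionSpec(framesTruth = cfg@framesTruth,
                             framesNoisy = frames,
                             muPerFrame = cfg@muPerFrame,
                             seed = cfg@masterSeed + i)
      say("scene %d @ %g MU: generating", i, mu)
      ds <- makeDataset(scene, acq, cfg@noise)
      noisyPsnr <- psnr(ds$truth, ds$noisy)
      npsOf <- function(img) {
        if (is.null(proi)) return(NULL)
        tryCatch(computeNPS(img, roiSize = cfg@npsRoiSize, region = proi),
                 error = function(e) NULL)
      }
      key0 <- sprintf("scene%d_mu%g", i, mu)
      npsNoisy <- npsOf(ds$noisy)
      if (!is.null(npsNoisy)) npsList[[paste0(key0, "_noisy")]] <- npsNoisy
      sh <- sharpness_row(ds$noisy, eroi)
      rows[[length(rows) + 1L]] <- data.frame(
        scene = i, mu = mu, filter = "noisy", bestParams = "",
        psnrNoisy = noisyPsnr, psnrDenoised = noisyPsnr,
        percentIncrease = 0, mtf50 = sh$mtf50, mtf10 = sh$mtf10,
        rise1090 = sh$rise1090, npsBandMean = nps_band_mean(npsNoisy))
      bgv <- var(as.vector(pixels(ds$noisy)[
        backgroundRegion(scene)[2]:(backgroundRegion(scene)[2] +
                                      backgroundRegion(scene)[4] - 1),
        backgroundRegion(scene)[1]:(backgroundRegion(scene)[1] +
                                      backgroundRegion(scene)[3] - 1)]))
      if (!isTRUE(bgv > 0)) bgv <- 1
      for (f in cfg@filters) {
        say("scene %d @ %g MU: sweeping %s", i, mu, f)
        res <- tryCatch({
          grid <- defaultGrid(f, backgroundVariance = bgv,
                              nPoints = cfg@gridPoints,
                              nPointsBilateral = cfg@bilateralGridPoints)
          withCallingHandlers(
            sweepFilter(ds$truth, ds$noisy, grid),
            warning = function(w) invokeRestart("muffleWarning"))
        }, error = function(e) NULL)
        if (is.null(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            scene = i, mu = mu, filter = f, bestParams = NA_character_,
            psnrNoisy = noisyPsnr, psnrDenoised = NA_real_,
            percentIncrease = NA_real_, mtf50 = NA_real_, mtf10 = NA_real_,
            rise1090 = NA_real_, npsBandMean = NA_real_)
          next
        }
        sweeps[[paste0(key0, "_", f)]] <- res@trace
        den <- denoise(ds$noisy, res@bestParams)
        npsDen <- npsOf(den)
        if (!is.null(npsDen)) npsList[[paste0(key0, "_", f)]] <- npsDen
        sh <- sharpness_row(den, eroi)
        sv <- swept_values(res@bestParams)
        rows[[length(rows) + 1L]] <- data.frame(
          scene = i, mu = mu, filter = f,
          bestParams = paste(names(sv), signif(unlist(sv), 6), sep = "=",
                             collapse = ","),
          psnrNoisy = res@noisyPsnr, psnrDenoised = res@bestPsnr,
          percentIncrease = res@percentIncrease, mtf50 = sh$mtf50,
          mtf10 = sh$mtf10, rise1090 = sh$rise1090,
          npsBandMean = nps_band_mean(npsDen))
      }
    }
  }
  metrics <- do.call(rbind, rows)
  anovaTab <- data.frame(mu = numeric(0), F = numeric(0), p = numeric(0))
  tukeyList <- list()
  if (cfg@withStats) {
    for (mu in cfg@muLevels) {
      sub <- metrics[metrics$mu == mu & metrics$filter != "noisy" &
                       is.finite(metrics$percentIncrease), ]
      groups <- split(sub$percentIncrease, sub$filter)
      groups <- groups[vapply(groups, length, 1L) >= 2L]
      if (length(groups) >= 2L) {
        a <- oneWayAnova(groups)
        anovaTab <- rbind(anovaTab,
                          data.frame(mu = mu, F = a$F, p = a$p))
        tukeyList[[as.character(mu)]] <- tukeyHsd(groups)
      }
    }
  }
  report <- new("BenchmarkReport", metrics = metrics, anova = anovaTab,
                tukey = tukeyList, sweeps = sweeps, nps = npsList,
                config = cfg, schemaVersion = "1.0")
  if (nzchar(cfg@outDir)) writeBenchmarkReport(report, cfg@outDir)
  report
}

#' Write a benchmark report's artifact files
#'
#' Emits `summary.csv` (the metrics table), one CSV per sweep trace under
#' `sweeps/`, one radial-NPS CSV per image under `nps/`, and `report.json`
#' with the comparison statistics.
#'
#' @param report a [BenchmarkReport-class].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
writeBenchmarkReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report@metrics, file.path(dir, "summary.csv"),
            row.names = FALSE)
  if (length(report@sweeps)) {
    dir.create(file.path(dir, "sweeps"), showWarnings = FALSE)
    for (k in names(report@sweeps))
      write.csv(report@sweeps[[k]],
                file.path(dir, "sweeps", paste0(k, ".csv")),
                row.names = FALSE)
  }
  if (length(report@nps)) {
    dir.create(file.path(dir, "nps"), showWarnings = FALSE)
    for (k in names(report@nps)) {
      n <- report@nps[[k]]
      write.csv(data.frame(freq_mm = n@radialFreqs, nps = n@radialValues,
                           std = n@radialStd),
                file.path(dir, "nps", paste0(k, ".csv")), row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(schema = report@schemaVersion,
         anova = report@anova,
         tukey = lapply(report@tukey, identity)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
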