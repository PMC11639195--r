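#' @include accessors.R
NULL

#' Write an image as 32-bit float TIFF with a JSON sidecar
#'
#' Intensities are stored normalized by their maximum (32-bit float TIFF
#' round-trips only values in the unit interval); the scale factor, pixel
#' pitch and any serializable metadata go to `<path>.json` so the image can
#' be restored losslessly up to float precision.
#'
#' @param img a [CherenkovImage-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeCherenkovTiff <- function(img, path) {
  stopifnot(is(img, "CherenkovImage"))
  px <- img@pixels
  scale <- max(px, 1e-12)
  tiff::writeTIFF(px / scale, path, bits.per.sample = 32L)
  side <- list(scale = scale, pixelPitch = img@pixelPitch,
               dim = dim(px),
               metadata = serializable_metadata(img@metadata))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image written by [writeCherenkovTiff()]
#'
#' @param path TIFF path (its `.json` sidecar must sit next to it).
#' @return a [CherenkovImage-class].
#' @export
readCherenkovTiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * side$scale
  cherenkovImage(px, pixelPitch = side$pixelPitch,
                 metadata = if (is.null(side$metadata)) list()
                            else as.list(side$metadata))
}

# drop metadata entries (S4 objects, matrices) that JSON cannot express
serializable_metadata <- function(md) {
  keep <- vapply(md, function(x)
    is.atomic(x) && length(x) <= 64L, logical(1))
  md[keep]
}

# specs -> plain lists, for JSON sidecars and the CLI
spec_to_list <- function(x) {
  sl <- methods::slotNames(class(x))
  out <- lapply(sl, function(s) methods::slot(x, s))
  names(out) <- sl
  out
}
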