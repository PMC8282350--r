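#' Calibrated multichannel field of view
#'
#' Container for a calibrated fluorescence field of view: one 2D intensity
#' matrix per channel role plus the pixel size in micrometers. Channels are
#' stored row-major with the origin at the top-left corner; all channels must
#' share dimensions. Recognized roles are `actinin`, `dapi`, `synapsin` and
#' `btx` (alpha-bungarotoxin), but arbitrary roles are accepted.
#'
#' @param channels named list of numeric matrices (intensity >= 0), one per
#'   channel role.
#' @param pixel_size_um pixel size in micrometers per pixel (isotropic).
#' @return object of class `fov` with fields `channels`, `pixel_size_um` and
#'   the derived `area_mm2`.
#' @examples
#' f <- fov(list(dapi = matrix(0, 64, 64)), pixel_size_um = 0.5)
#' f$area_mm2  # 64*64*0.5^2 * 1e-6
#' @export
fov <- function(channels, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all channels must be matrices")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all channels must share dimensions")
  structure(
    list(channels = channels,
         pixel_size_um = pixel_size_um,
         area_mm2 = prod(d1) * pixel_size_um^2 * 1e-6),
    class = "fov")
}

#' @export
print.fov <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<fov> %d x %d px @ %.4g um/px (%.4g mm^2); channels: %s\n",
              d[1], d[2], x$pixel_size_um, x$area_mm2,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write / read a field of view as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per channel (32-bit float, intensities clipped to `[0,1]`
#' for storage) and a JSON sidecar recording channel roles and the pixel
#' size, so a round trip preserves calibration.
#'
#' @param x an [fov] object.
#' @param path path of the `.tif` file; the sidecar is written next to it
#'   with extension `.json`.
#' @return `write_fov` returns `path` invisibly; `read_fov` returns an [fov].
#' @export
write_fov <- function(x, path) {
  stopifnot(inherits(x, "fov"))
  pages <- lapply(x$channels, function(m) clip(m, 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(pixel_size_um = x$pixel_size_um, channels = names(x$channels))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fov
#' @param path path of a `.tif` written by [write_fov()].
#' @export
read_fov <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  names(pages) <- meta$channels
  fov(pages, pixel_size_um = meta$pixel_size_um)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
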