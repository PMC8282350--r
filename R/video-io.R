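#' Write / read an MTF frame stack as multi-page TIFF plus JSON metadata
#'
#' One page per frame; the sidecar records fps, pixel size, film ROIs,
#' film length, twitch pacing rate, stimulus schedule and the Stoney
#' geometry, so [analyze_mtf()] can run on a re-read video.
#'
#' @param video list with `frames` and `meta` as from [make_mtf_video()].
#' @param path path of the `.tif` file (sidecar written next to it).
#' @return `write_mtf_video` returns `path` invisibly; `read_mtf_video` a
#'   list with `frames` and `meta`.
#' @export
write_mtf_video <- function(video, path) {
  n <- dim(video$frames)[3]
  pages <- lapply(seq_len(n), function(k) clip(video$frames[, , k], 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  m <- video$meta
  jsonlite::write_json(
    list(fps = m$fps, pixel_size_mm = m$pixel_size_mm, rois = m$rois,
         film_length_mm = m$film_length_mm,
         schedule = m$schedule, twitch_rate_hz = m$twitch_rate_hz,
         geometry = unclass(m$geometry)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mtf_video
#' @export
read_mtf_video <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  meta$rois <- lapply(seq_len(nrow(meta$rois)), function(i) as.list(meta$rois[i, ]))
  meta$geometry <- do.call(mtf_geometry, as.list(meta$geometry))
  list(frames = frames, meta = meta)
}
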