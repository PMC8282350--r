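#' Presynaptic (synapsin) area mask
#'
#' Otsu-thresholds the synapsin-1 channel, removes objects smaller than
#' `min_object_um2`, and fills holes (axon bundles often enclose unstained
#' interiors that belong to the presynaptic footprint). Returns the binary
#' mask and its area as a percentage of the field.
#'
#' @param fov an [fov] with a `synapsin` channel.
#' @param min_object_um2 smallest retained object, um^2.
#' @return list with `mask` (logical matrix) and `area_pct` in `[0, 100]`.
#'   A blank channel yields an empty mask and 0%.
#' @export
synapsin_mask <- function(fov, min_object_um2 = 5) {
  stopifnot(inherits(fov, "fov"), "synapsin" %in% names(fov$channels))
  chan <- fov$channels$synapsin
  thr <- otsu_threshold(chan)
  if (!is.finite(thr))
    return(list(mask = matrix(FALSE, nrow(chan), ncol(chan)), area_pct = 0))
  lc <- label_components(chan > thr)
  keep <- which(lc$areas_px * fov$pixel_size_um^2 >= min_object_um2)
  mask <- matrix(lc$labels %in% keep, nrow(chan), ncol(chan))
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(1 * mask))) > 0.5
  list(mask = mask, area_pct = 100 * mean(mask))
}

#' Postsynaptic (bungarotoxin) receptor clusters
#'
#' Otsu-thresholds the bungarotoxin channel, labels connected components and
#' discards those below `min_cluster_um2`. The minimum cluster size is
#' configurable (4 um^2 by default).
#'
#' @param fov an [fov] with a `btx` channel.
#' @param min_cluster_um2 smallest retained cluster, um^2.
#' @return list with `clusters` (data frame: `id`, `area_um2`, `row_px`,
#'   `col_px`), `labels` (labeled matrix, original labels), `area_pct`
#'   (total thresholded bungarotoxin area % before the size filter).
#' @export
btx_clusters <- function(fov, min_cluster_um2 = 4) {
  stopifnot(inherits(fov, "fov"), "btx" %in% names(fov$channels))
  chan <- fov$channels$btx
  thr <- otsu_threshold(chan)
  empty <- data.frame(id = integer(0), area_um2 = numeric(0),
                      row_px = numeric(0), col_px = numeric(0))
  if (!is.finite(thr))
    return(list(clusters = empty,
                labels = matrix(0L, nrow(chan), ncol(chan)), area_pct = 0))
  lc <- label_components(chan > thr)
  area_pct <- 100 * sum(lc$areas_px) / length(chan)
  areas_um2 <- lc$areas_px * fov$pixel_size_um^2
  keep <- which(areas_um2 >= min_cluster_um2)
  cen <- component_centroids(lc$labels)
  list(clusters = data.frame(id = keep,
                             area_um2 = areas_um2[keep],
                             row_px = cen[keep, "row"],
                             col_px = cen[keep, "col"]),
       labels = lc$labels, area_pct = area_pct)
}

#' Percentage of bungarotoxin clusters co-localized with synapsin
#'
#' A cluster counts as co-localized when at least one of its pixels (or,
#' with `overlap_frac > 0`, at least that fraction of its pixels) overlaps
#' the synapsin mask after dilating the mask by `dilate_px` pixels — a
#' registration tolerance for sub-pixel channel misalignment. With zero
#' clusters the percentage is undefined and signaled as `NA`, never as 0.
#'
#' @param clusters a [btx_clusters()] result.
#' @param syn_mask logical matrix from [synapsin_mask()] (same field size).
#' @param dilate_px dilation radius applied to the synapsin mask (px).
#' @param overlap_frac minimum overlapping fraction of cluster pixels
#'   (0 means any single pixel).
#' @return percentage in `[0, 100]`, or `NA` with `reason` when there are
#'   no clusters.
#' @export
colocalization <- function(clusters, syn_mask, dilate_px = 1,
                           overlap_frac = 0) {
  stopifnot(identical(dim(clusters$labels), dim(syn_mask)))
  ids <- clusters$clusters$id
  if (length(ids) == 0) return(undefined_result("zero bungarotoxin clusters"))
  mask <- syn_mask
  if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, "box")
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(1 * syn_mask),
                                               brush)) > 0.5
  }
  hit <- vapply(ids, function(id) {
    px <- clusters$labels == id
    ov <- sum(mask & px)
    if (overlap_frac > 0) ov / sum(px) >= overlap_frac else ov >= 1
  }, logical(1))
  100 * mean(hit)
}

#' All NMJ structural metrics for one field of view
#'
#' @param fov an [fov] with `synapsin` and `btx` channels.
#' @param min_cluster_um2 passed to [btx_clusters()].
#' @param ... passed to [colocalization()].
#' @return object of class `nmj_metrics`: `synapsin_area_pct`,
#'   `btx_area_pct`, `btx_cluster_areas_um2`, `coloc_pct` (`NA` with reason
#'   when no clusters).
#' @export
nmj_metrics <- function(fov, min_cluster_um2 = 4, ...) {
  syn <- synapsin_mask(fov)
  cl <- btx_clusters(fov, min_cluster_um2 = min_cluster_um2)
  structure(list(synapsin_area_pct = syn$area_pct,
                 btx_area_pct = cl$area_pct,
                 btx_cluster_areas_um2 = cl$clusters$area_um2,
                 coloc_pct = colocalization(cl, syn$mask, ...)),
            class = "nmj_metrics")
}

#' @export
print.nmj_metrics <- function(x, ...) {
  cat(sprintf("<nmj_metrics> synapsin %.1f%% | btx %.1f%% | %d clusters (mean %.1f um^2) | coloc %s\n",
              x$synapsin_area_pct, x$btx_area_pct,
              length(x$btx_cluster_areas_um2),
              if (length(x$btx_cluster_areas_um2)) mean(x$btx_cluster_areas_um2) else NA,
              if (is.na(x$coloc_pct)) "undefined" else sprintf("%.0f%%", x$coloc_pct)))
  invisible(x)
}
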