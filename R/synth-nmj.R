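#' Render a synthetic NMJ field with a programmed co-localization fraction
#'
#' Renders a two-channel field emulating NMJ immunostains: the bungarotoxin
#' channel contains `n_clusters` disjoint circular receptor clusters of the
#' stated area, and the synapsin channel contains a presynaptic region
#' occupying `synapsin_area_fraction` of the field. Exactly
#' `round(coloc_fraction * n_clusters)` clusters are placed inside the
#' synapsin region (overlapping it fully); the remainder are placed at least
#' `clearance_um` away from it, so the programmed co-localization fraction is
#' recoverable exactly on noiseless fields.
#'
#' @param coloc_fraction fraction of clusters co-localized with synapsin, in
#'   `[0, 1]`.
#' @param n_clusters number of bungarotoxin clusters.
#' @param cluster_area_um2 area of each cluster in um^2.
#' @param synapsin_area_fraction fraction of the field covered by the
#'   synapsin region, in `(0, 1)`.
#' @param seed integer RNG seed.
#' @param field_size_um field height and width in um.
#' @param pixel_size_um pixel size in um/px.
#' @param noise_sd additive Gaussian noise SD on both channels (clipped to
#'   `[0, 1]`).
#' @param clearance_um minimum gap between non-co-localized clusters and the
#'   synapsin region (must exceed the 1 px registration dilation used by
#'   [colocalization()]).
#' @return list with `fov` (channels `synapsin`, `btx`) and `truth`
#'   (recording cluster centers, radius and which clusters are co-localized).
#' @export
make_nmj_image <- function(coloc_fraction, n_clusters = 10,
                           cluster_area_um2 = 20,
                           synapsin_area_fraction = 0.15,
                           seed = 1,
                           field_size_um = c(100, 100),
                           pixel_size_um = 0.2,
                           noise_sd = 0,
                           clearance_um = 2) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1, n_clusters >= 1,
            cluster_area_um2 > 0, synapsin_area_fraction > 0,
            synapsin_area_fraction < 1, noise_sd >= 0)
  px <- pixel_size_um
  ny <- round(field_size_um[1] / px)
  nx <- round(field_size_um[2] / px)
  r_px <- sqrt(cluster_area_um2 / pi) / px
  if (n_clusters * cluster_area_um2 > 0.25 * prod(field_size_um))
    stop("invalid spec: requested cluster area exceeds a quarter of the field")

  ## Synapsin region: vertical band at the left of the field.
  band_cols <- max(1L, round(synapsin_area_fraction * nx))
  syn <- matrix(0, ny, nx)
  syn[, seq_len(band_cols)] <- 0.8

  n_coloc <- round(coloc_fraction * n_clusters)
  clear_px <- clearance_um / px

  with_rng_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    sep <- 2 * r_px + 3
    place <- function(n, c_lo, c_hi) {
      if (c_hi <= c_lo) stop("invalid spec: no room for clusters in region")
      placed <- 0L; tries <- 0L
      while (placed < n && tries < n * 1000L) {
        tries <- tries + 1L
        r <- runif(1, r_px + 2, ny - r_px - 2)
        c <- runif(1, c_lo, c_hi)
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2)) >= sep) {
          centers <<- rbind(centers, c(r, c))
          placed <- placed + 1L
        }
      }
      if (placed < n)
        stop("invalid spec: could not place disjoint clusters in the field")
    }
    ## Co-localized clusters entirely inside the band; the rest clear of it.
    if (n_coloc > 0) place(n_coloc, r_px + 2, band_cols - r_px - 1)
    if (n_clusters - n_coloc > 0)
      place(n_clusters - n_coloc, band_cols + r_px + clear_px + 2, nx - r_px - 2)
    coloc_flag <- c(rep(TRUE, n_coloc), rep(FALSE, n_clusters - n_coloc))

    btx <- matrix(0, ny, nx)
    rows <- row(btx); cols <- col(btx)
    for (k in seq_len(nrow(centers))) {
      d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
      btx[d2 <= r_px^2] <- 0.9
    }

    if (noise_sd > 0) {
      syn <- clip(syn + rnorm(length(syn), 0, noise_sd), 0, 1)
      btx <- clip(btx + rnorm(length(btx), 0, noise_sd), 0, 1)
    }

    truth <- synthetic_truth(
      "nmj_image",
      params = list(coloc_fraction = coloc_fraction,
                    n_clusters = n_clusters,
                    n_coloc = n_coloc,
                    cluster_area_um2 = cluster_area_um2,
                    cluster_radius_px = r_px,
                    synapsin_area_fraction = band_cols / nx,
                    centers_row_px = centers[, 1],
                    centers_col_px = centers[, 2],
                    coloc = coloc_flag,
                    pixel_size_um = px,
                    noise_sd = noise_sd),
      seed = seed)

    list(fov = fov(list(synapsin = syn, btx = btx), pixel_size_um = px),
         truth = truth)
  })
}
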