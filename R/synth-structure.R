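#' Specification for a synthetic striated-muscle field of view
#'
#' Describes a field of aligned myotubes with a raised-cosine striation along
#' the fiber axis (the alpha-actinin channel) and elliptical nuclei blobs
#' (the DAPI channel). The striation model is
#' `I(x) = base * (1 + c * cos(2*pi*x / p))` with period `p =
#' sarcomere_spacing_um` and contrast `c`, so the fundamental spatial
#' frequency of the rendered pattern is exactly `1/p` cycles per micrometer.
#'
#' @param field_size_um numeric pair, field height and width in um.
#' @param pixel_size_um pixel size in um/px; the sarcomere spacing must be at
#'   least `2 * pixel_size_um` (Nyquist).
#' @param n_myotubes number of parallel myotube stripes.
#' @param myotube_width_um stripe width in um (scalar, or one value per
#'   myotube).
#' @param sarcomere_spacing_um striation period in um.
#' @param striation_contrast contrast `c` in `[0, 1]`; 0 renders uniform
#'   stripes with no periodic signal.
#' @param n_nuclei number of nuclei blobs.
#' @param fraction_nuclei_in_myotubes fraction of nuclei whose centers fall
#'   inside myotube footprints.
#' @param noise_sd additive Gaussian noise SD (intensity units; images are
#'   clipped to `[0, 1]`).
#' @param nucleus_sigma_um Gaussian semi-axes (along, across fiber) of a
#'   nucleus blob in um.
#' @param min_nucleus_separation_um minimum center-to-center distance between
#'   nuclei, so blobs stay resolvable as separate components.
#' @return object of class `structure_image_spec`.
#' @export
structure_image_spec <- function(field_size_um = c(200, 200),
                                 pixel_size_um = 0.2,
                                 n_myotubes = 4,
                                 myotube_width_um = 20,
                                 sarcomere_spacing_um = 2,
                                 striation_contrast = 0.5,
                                 n_nuclei = 120,
                                 fraction_nuclei_in_myotubes = 0.7,
                                 noise_sd = 0.02,
                                 nucleus_sigma_um = c(2.5, 1.8),
                                 min_nucleus_separation_um = 8) {
  stopifnot(length(field_size_um) == 2, all(field_size_um > 0),
            pixel_size_um > 0, n_myotubes >= 1, all(myotube_width_um > 0),
            sarcomere_spacing_um > 0,
            striation_contrast >= 0, striation_contrast <= 1,
            n_nuclei >= 0, fraction_nuclei_in_myotubes >= 0,
            fraction_nuclei_in_myotubes <= 1, noise_sd >= 0)
  if (sarcomere_spacing_um < 2 * pixel_size_um)
    stop("invalid spec: sarcomere_spacing_um below the Nyquist limit of 2 pixels")
  structure(as.list(environment()), class = "structure_image_spec")
}

#' Render a synthetic striated-muscle field of view with ground truth
#'
#' Renders the alpha-actinin and DAPI channels described by a
#' [structure_image_spec()]: `n_myotubes` horizontal stripes of the stated
#' width whose along-axis intensity is a raised cosine of period
#' `sarcomere_spacing_um`, plus elliptical Gaussian nuclei with the stated
#' fraction centered inside myotube footprints, plus clipped additive
#' Gaussian noise. The same `(spec, seed)` pair reproduces the identical
#' image.
#'
#' @param spec a [structure_image_spec()].
#' @param seed integer RNG seed.
#' @return list with elements `fov` (an [fov] with `actinin` and `dapi`
#'   channels) and `truth` (a [synthetic_truth] recording stripe rows/widths,
#'   nucleus centers and in-myotube flags).
#' @export
make_structure_image <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "structure_image_spec"))
  px <- spec$pixel_size_um
  ny <- round(spec$field_size_um[1] / px)
  nx <- round(spec$field_size_um[2] / px)
  widths <- rep(spec$myotube_width_um, length.out = spec$n_myotubes)
  w_px <- round(widths / px)
  slot <- ny / spec$n_myotubes
  if (any(w_px >= slot))
    stop("invalid spec: myotubes too wide to place without overlap")

  with_rng_seed(seed, {
    actinin <- matrix(0, ny, nx)
    dapi <- matrix(0, ny, nx)

    ## Stripe placement: one stripe per vertical slot, jittered within it.
    stripe_rows <- matrix(0L, spec$n_myotubes, 2)
    for (i in seq_len(spec$n_myotubes)) {
      lo <- (i - 1) * slot
      jit <- runif(1, 0.1, 0.9) * (slot - w_px[i])
      r0 <- round(lo + jit) + 1L
      r1 <- r0 + w_px[i] - 1L
      stripe_rows[i, ] <- c(r0, r1)
    }

    ## Raised-cosine striation along x (fiber axis horizontal).
    x_um <- (seq_len(nx) - 0.5) * px
    base <- 0.5
    stria <- base * (1 + spec$striation_contrast *
                       cos(2 * pi * x_um / spec$sarcomere_spacing_um))
    for (i in seq_len(spec$n_myotubes))
      actinin[stripe_rows[i, 1]:stripe_rows[i, 2], ] <-
        matrix(stria, nrow = w_px[i], ncol = nx, byrow = TRUE)

    ## Nuclei: rejection-sample centers with a minimum separation; the
    ## requested fraction inside stripe footprints, the rest outside with a
    ## small margin.
    n_in <- round(spec$fraction_nuclei_in_myotubes * spec$n_nuclei)
    n_out <- spec$n_nuclei - n_in
    sep_px <- spec$min_nucleus_separation_um / px
    margin <- ceiling(3 * max(spec$nucleus_sigma_um) / px)
    in_rows <- unlist(lapply(seq_len(spec$n_myotubes), function(i) {
      r <- stripe_rows[i, ]
      if (diff(r) > 4) (r[1] + 2):(r[2] - 2) else integer(0)
    }))
    all_rows <- seq_len(ny)
    stripe_mask_rows <- unlist(lapply(seq_len(spec$n_myotubes), function(i)
      stripe_rows[i, 1]:stripe_rows[i, 2]))
    out_rows <- setdiff(all_rows, unique(unlist(lapply(stripe_mask_rows, function(r)
      max(1, r - margin %/% 2):min(ny, r + margin %/% 2)))))
    out_rows <- out_rows[out_rows > margin & out_rows < ny - margin]
    if (n_in > 0 && length(in_rows) == 0)
      stop("invalid spec: no room for nuclei inside myotubes")
    if (n_out > 0 && length(out_rows) == 0)
      stop("invalid spec: no room for nuclei outside myotubes")

    centers <- matrix(numeric(0), 0, 2)
    place <- function(n, rows) {
      placed <- 0L
      tries <- 0L
      while (placed < n && tries < n * 400L) {
        tries <- tries + 1L
        r <- sample(rows, 1)
        c <- runif(1, margin, nx - margin)
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2)) >= sep_px) {
          centers <<- rbind(centers, c(r, c))
          placed <- placed + 1L
        }
      }
      if (placed < n)
        stop("invalid spec: could not place nuclei with the requested separation")
    }
    place(n_in, in_rows)
    place(n_out, out_rows)
    in_flag <- c(rep(TRUE, n_in), rep(FALSE, n_out))

    sr <- spec$nucleus_sigma_um[2] / px  # across-fiber sigma (rows)
    sc <- spec$nucleus_sigma_um[1] / px  # along-fiber sigma (cols)
    if (nrow(centers) > 0) {
      for (k in seq_len(nrow(centers))) {
        r0 <- max(1, floor(centers[k, 1] - 3 * sr))
        r1 <- min(ny, ceiling(centers[k, 1] + 3 * sr))
        c0 <- max(1, floor(centers[k, 2] - 3 * sc))
        c1 <- min(nx, ceiling(centers[k, 2] + 3 * sc))
        rr <- r0:r1; cc <- c0:c1
        blob <- exp(-0.5 * (outer((rr - centers[k, 1])^2 / sr^2,
                                  (cc - centers[k, 2])^2 / sc^2, "+")))
        dapi[rr, cc] <- pmax(dapi[rr, cc], blob)
      }
    }

    if (spec$noise_sd > 0) {
      actinin <- actinin + rnorm(length(actinin), 0, spec$noise_sd)
      dapi <- dapi + rnorm(length(dapi), 0, spec$noise_sd)
    }
    actinin <- clip(actinin, 0, 1)
    dapi <- clip(dapi, 0, 1)

    truth <- synthetic_truth(
      "structure_image",
      params = list(
        field_size_um = spec$field_size_um, pixel_size_um = px,
        n_myotubes = spec$n_myotubes, myotube_width_um = widths,
        sarcomere_spacing_um = spec$sarcomere_spacing_um,
        striation_contrast = spec$striation_contrast,
        n_nuclei = spec$n_nuclei,
        fraction_nuclei_in_myotubes = spec$fraction_nuclei_in_myotubes,
        noise_sd = spec$noise_sd,
        stripe_rows = stripe_rows,
        nuclei_row_px = centers[, 1], nuclei_col_px = centers[, 2],
        nuclei_in_myotube = in_flag,
        nuclei_per_mm2 = spec$n_nuclei /
          (ny * nx * px^2 * 1e-6)),
      seed = seed)

    list(fov = fov(list(actinin = actinin, dapi = dapi), pixel_size_um = px),
         truth = truth)
  })
}
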