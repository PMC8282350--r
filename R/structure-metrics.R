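#' Nuclei density from the DAPI channel
#'
#' Otsu-thresholds the DAPI channel (threshold computed over the observed
#' intensity range, so the count is invariant under uniform intensity
#' scaling), labels connected components, keeps components whose area falls
#' in `[min_area_um2, max_area_um2]`, and divides the count by the field
#' area in mm^2. Size bounds are configurable because the original analyses
#' of this assay did not publish theirs.
#'
#' @param fov an [fov] with a `dapi` channel.
#' @param min_area_um2,max_area_um2 nucleus area bounds in um^2.
#' @return nuclei per mm^2 (scalar). A blank or constant channel returns 0
#'   with a warning.
#' @export
count_nuclei <- function(fov, min_area_um2 = 20, max_area_um2 = 500) {
  stopifnot(inherits(fov, "fov"), "dapi" %in% names(fov$channels))
  dapi <- fov$channels$dapi
  thr <- otsu_threshold(dapi)
  if (!is.finite(thr)) {
    warning("DAPI channel is empty or constant; returning 0 nuclei")
    return(0)
  }
  lc <- label_components(dapi > thr)
  areas_um2 <- lc$areas_px * fov$pixel_size_um^2
  sum(areas_um2 >= min_area_um2 & areas_um2 <= max_area_um2) / fov$area_mm2
}

## Otsu myotube mask with morphological closing bridging the striation
## troughs (closing diameter in um so behavior is scale-independent).
actinin_mask <- function(act, pixel_size_um, close_um = 3) {
  thr <- otsu_threshold(act)
  if (!is.finite(thr)) return(matrix(FALSE, nrow(act), ncol(act)))
  brush <- odd_window(close_um / pixel_size_um)
  mask <- EBImage::closing(EBImage::Image(1 * (act > thr)),
                           EBImage::makeBrush(brush, "disc"))
  EBImage::imageData(mask) > 0.5
}

## Labeled nuclei passing the size filter; internal, shared by
## count_nuclei-style ops and myogenic_index.
nuclei_centroids <- function(fov, min_area_um2 = 20, max_area_um2 = 500) {
  dapi <- fov$channels$dapi
  thr <- otsu_threshold(dapi)
  if (!is.finite(thr))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  lc <- label_components(dapi > thr)
  areas_um2 <- lc$areas_px * fov$pixel_size_um^2
  keep <- which(areas_um2 >= min_area_um2 & areas_um2 <= max_area_um2)
  cen <- component_centroids(lc$labels)
  cen[keep, , drop = FALSE]
}

#' Myogenic index: fraction of nuclei inside the myotube mask
#'
#' The myotube mask is the Otsu-thresholded alpha-actinin channel after
#' morphological closing (5 px disc, bridging the striation troughs); a
#' nucleus counts as inside when its centroid lies in the mask. With zero
#' nuclei the index is undefined and signaled as `NA` (never reported as 0).
#'
#' @param fov an [fov] with `actinin` and `dapi` channels.
#' @param min_area_um2,max_area_um2 nucleus size filter, as in
#'   [count_nuclei()].
#' @return proportion in `[0, 1]`, or `NA` (with attribute `reason`) when no
#'   nuclei are present.
#' @export
myogenic_index <- function(fov, min_area_um2 = 20, max_area_um2 = 500) {
  stopifnot(inherits(fov, "fov"),
            all(c("actinin", "dapi") %in% names(fov$channels)))
  cen <- nuclei_centroids(fov, min_area_um2, max_area_um2)
  if (nrow(cen) == 0) return(undefined_result("zero nuclei detected"))
  act <- fov$channels$actinin
  if (!is.finite(otsu_threshold(act))) return(0)  # nuclei, no myotube signal
  mask <- actinin_mask(act, fov$pixel_size_um)
  inside <- mask[cbind(pmin(pmax(round(cen[, 1]), 1), nrow(mask)),
                       pmin(pmax(round(cen[, 2]), 1), ncol(mask)))]
  mean(inside)
}

#' Mean myotube width from randomly sampled sub-fields
#'
#' Samples `n_fields` random square sub-fields of `field_area_mm2` from the
#' alpha-actinin channel, segments the myotube mask (global Otsu threshold),
#' and measures each object's width as twice the median distance-transform
#' value along its medial axis (the distance-ridge: pixels whose Euclidean
#' distance to background is a local maximum). Returns the grand mean over
#' all objects in all sub-fields. The distance-transform estimator replaces
#' the manual width measurements of the original assay and is invariant to
#' image rotation.
#'
#' @param fov an [fov] with an `actinin` channel.
#' @param n_fields number of random sub-fields.
#' @param field_area_mm2 area of each square sub-field in mm^2 (clipped to
#'   the full field when larger).
#' @param min_object_um2 smallest object measured, in um^2.
#' @param seed optional seed making the sub-field sampling reproducible.
#' @return mean myotube width in um, or `NA` (with `reason`) when no
#'   myotube objects are found.
#' @export
myotube_width <- function(fov, n_fields = 5, field_area_mm2 = 0.1,
                          min_object_um2 = 50, seed = NULL) {
  stopifnot(inherits(fov, "fov"), "actinin" %in% names(fov$channels))
  act <- fov$channels$actinin
  px <- fov$pixel_size_um
  if (!is.finite(otsu_threshold(act)))
    return(undefined_result("no myotube objects found"))
  mask_full <- actinin_mask(act, px)

  side_px <- round(sqrt(field_area_mm2 * 1e6) / px)
  ny <- nrow(act); nx <- ncol(act)
  side_px <- min(side_px, ny, nx)

  sample_fields <- function() {
    widths <- numeric(0)
    for (k in seq_len(n_fields)) {
      r0 <- if (ny > side_px) sample.int(ny - side_px, 1) else 1L
      c0 <- if (nx > side_px) sample.int(nx - side_px, 1) else 1L
      sub <- mask_full[r0:(r0 + side_px - 1), c0:(c0 + side_px - 1)]
      lc <- label_components(sub)
      if (length(lc$areas_px) == 0) next
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 * sub)))
      for (obj in which(lc$areas_px * px^2 >= min_object_um2)) {
        sel <- lc$labels == obj
        dobj <- dm * sel
        ridge <- dobj >= ridge_local_max(dobj) & sel & dobj > 0
        if (!any(ridge)) next
        widths <- c(widths, (2 * median(dm[ridge]) - 0.5) * px)
      }
    }
    widths
  }
  widths <- if (is.null(seed)) sample_fields() else with_rng_seed(seed, sample_fields())
  if (length(widths) == 0) return(undefined_result("no myotube objects found"))
  mean(widths)
}

## 3x3 neighborhood maximum (for distance-ridge extraction).
ridge_local_max <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  out <- matrix(-Inf, ny, nx)
  for (dr in -1:1) for (dc in -1:1)
    out <- pmax(out, pad[(2 + dr):(ny + 1 + dr), (2 + dc):(nx + 1 + dc)])
  out
}

#' Radially collapsed 2D FFT power spectrum of a myotube section
#'
#' Computes the mean-subtracted 2D FFT power of a myotube crop, collapses
#' `|F|^2` radially by averaging over annuli of one FFT frequency step in
#' spatial-frequency magnitude, excludes the DC bin, and normalizes the
#' resulting 1D profile to unit trapezoidal integral. Frequencies are in
#' cycles per micrometer, so a striation of period `p` um produces a peak
#' at `1/p`.
#'
#' @param section 2D intensity matrix (a myotube crop, nominally 50 um
#'   wide), at least 8 x 8 px.
#' @param pixel_size_um pixel size in um/px.
#' @return object of class `power_spectrum_profile`: list with
#'   `frequency_per_um` (increasing bin centers) and `power` (unit-integral
#'   normalized).
#' @export
radial_power_spectrum <- function(section, pixel_size_um) {
  if (is.null(dim(section)) || any(dim(section) < 8))
    stop("invalid input: section must be at least 8x8 px")
  stopifnot(pixel_size_um > 0)
  z <- section - mean(section)
  P <- Mod(fft(z))^2
  ny <- nrow(z); nx <- ncol(z)
  fy <- ((seq_len(ny) - 1) - ny * ((seq_len(ny) - 1) >= ny / 2)) / (ny * pixel_size_um)
  fx <- ((seq_len(nx) - 1) - nx * ((seq_len(nx) - 1) >= nx / 2)) / (nx * pixel_size_um)
  fmag <- sqrt(outer(fy^2, fx^2, "+"))
  df <- 1 / (max(ny, nx) * pixel_size_um)
  f_nyq <- 1 / (2 * pixel_size_um)
  bin <- round(fmag / df)
  keep <- bin > 0 & fmag <= f_nyq
  power <- vapply(split(P[keep], bin[keep]), mean, numeric(1))
  freq <- as.numeric(names(power)) * df
  o <- order(freq)
  freq <- freq[o]; power <- power[o]
  area <- pracma::trapz(freq, power)
  if (area > 0) power <- power / area
  structure(list(frequency_per_um = freq, power = power),
            class = "power_spectrum_profile")
}

#' Sarcomere index: periodic fraction of a power-spectrum profile
#'
#' Decomposes a unit-integral radial power-spectrum profile into an
#' aperiodic component `a * exp(-b * f)` and a periodic component that is a
#' sum of Gaussians (default two: the striation fundamental plus its first
#' harmonic, with the harmonic center constrained to twice the fundamental
#' within 10%), by Levenberg-Marquardt least squares. The sarcomere index
#' is the integral of the fitted periodic component, clipped to `[0, 1]`:
#' 0 for an unstriated myotube, approaching 1 when nearly all spectral mass
#' is periodic. Initialization is deterministic: the aperiodic start comes
#' from a log-linear regression of the profile and the Gaussian center from
#' the residual argmax. If the fit fails to converge the aperiodic-only
#' model is kept, the index is 0, and `converged` is `FALSE`.
#'
#' @param profile a [radial_power_spectrum()] result.
#' @param n_gaussians 1 (fundamental only) or 2 (fundamental + harmonic).
#' @param max_width_per_um upper bound on the Gaussian widths (cycles/um).
#'   Striation peaks are spectrally narrow; the cap keeps the periodic
#'   component from absorbing broad aperiodic structure and makes the
#'   decomposition identifiable on noise-dominated profiles.
#' @param min_center_per_um lower bound on the fundamental's center
#'   (cycles/um). Striation periods beyond ~5 um are not physiological, and
#'   the lowest-frequency annuli of the radial collapse average very few
#'   pixels, so leaving them available to the Gaussian lets it chase
#'   low-frequency noise.
#' @return object of class `spectrum_fit`: `aperiodic_amp`,
#'   `aperiodic_rate`, `gaussian_components` (data frame amplitude /
#'   center_per_um / width_per_um), `sarcomere_index`, `converged`.
#' @export
sarcomere_index <- function(profile, n_gaussians = 2, max_width_per_um = 0.15,
                            min_center_per_um = 0.2) {
  stopifnot(inherits(profile, "power_spectrum_profile"),
            n_gaussians %in% c(1, 2))
  f <- profile$frequency_per_um
  y <- profile$power
  df <- median(diff(f))
  s_max <- max(max_width_per_um, df)

  ## deterministic starts
  co <- coef(lm(log(pmax(y, 1e-12)) ~ f))
  a0 <- max(exp(co[1]), 1e-8)
  b0 <- max(-co[2], 1e-6)
  c_min <- max(2 * df, min_center_per_um)
  resid0 <- y - a0 * exp(-b0 * f)
  resid_hi <- ifelse(f >= c_min, resid0, -Inf)
  c0 <- max(f[which.max(resid_hi)], c_min)
  A0 <- max(max(resid0), 1e-8)
  s0 <- min(2 * df, s_max)

  ## Residual-function interface: robust when a Gaussian amplitude
  ## legitimately converges to 0 (e.g. a striation with no harmonic), which
  ## makes the model gradient singular in that component's shape parameters.
  model2 <- function(p) p["a"] * exp(-p["b"] * f) +
    p["A1"] * exp(-(f - p["c1"])^2 / (2 * p["s1"]^2)) +
    p["A2"] * exp(-(f - p["h"] * p["c1"])^2 / (2 * p["s2"]^2))
  model1 <- function(p) p["a"] * exp(-p["b"] * f) +
    p["A1"] * exp(-(f - p["c1"])^2 / (2 * p["s1"]^2))
  if (n_gaussians == 2) {
    start <- c(a = a0, b = b0, A1 = A0, c1 = c0, s1 = s0, A2 = A0 / 4,
               h = 2, s2 = s0)
    lower <- c(a = 0, b = 1e-6, A1 = 0, c1 = c_min, s1 = df / 2, A2 = 0,
               h = 1.8, s2 = df / 2)
    upper <- c(a = Inf, b = Inf, A1 = Inf, c1 = max(f), s1 = s_max, A2 = Inf,
               h = 2.2, s2 = s_max)
    model <- model2
  } else {
    start <- c(a = a0, b = b0, A1 = A0, c1 = c0, s1 = s0)
    lower <- c(a = 0, b = 1e-6, A1 = 0, c1 = c_min, s1 = df / 2)
    upper <- c(a = Inf, b = Inf, A1 = Inf, c1 = max(f), s1 = s_max)
    model <- model1
  }
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) y - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)

  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(structure(list(aperiodic_amp = a0, aperiodic_rate = b0,
                          gaussian_components = data.frame(
                            amplitude = numeric(0), center_per_um = numeric(0),
                            width_per_um = numeric(0)),
                          sarcomere_index = 0, converged = FALSE),
                     class = "spectrum_fit"))
  }
  cf <- as.list(coef(fit))
  comps <- if (n_gaussians == 2) {
    data.frame(amplitude = c(cf$A1, cf$A2),
               center_per_um = c(cf$c1, cf$h * cf$c1),
               width_per_um = c(cf$s1, cf$s2))
  } else {
    data.frame(amplitude = cf$A1, center_per_um = cf$c1, width_per_um = cf$s1)
  }
  periodic <- rowSums(vapply(seq_len(nrow(comps)), function(i)
    comps$amplitude[i] * exp(-(f - comps$center_per_um[i])^2 /
                               (2 * comps$width_per_um[i]^2)),
    numeric(length(f))))
  idx <- clip(pracma::trapz(f, periodic), 0, 1)
  structure(list(aperiodic_amp = cf$a, aperiodic_rate = cf$b,
                 gaussian_components = comps,
                 sarcomere_index = idx, converged = TRUE),
            class = "spectrum_fit")
}

#' Sarcomere length from z-disc band spacing
#'
#' Estimates the fiber orientation from intensity moments (rotating the
#' section when it deviates from horizontal by more than 1 degree),
#' averages intensity column-wise along the fiber axis, detects peaks
#' (z-disc bands) with a minimum prominence of `0.1 x` the profile range and
#' a minimum separation of 1.5 um, refines each peak position by 3-point
#' parabolic interpolation, and reports the median inter-peak spacing.
#' Fewer than 3 peaks — e.g. an unstriated myotube — yields an undefined
#' result. Lengths outside the healthy vertebrate range `[1.8, 2.4]` um are
#' flagged via the `in_physiological_range` attribute.
#'
#' @param section 2D intensity matrix, fiber axis within ~15 degrees of
#'   horizontal.
#' @param pixel_size_um pixel size in um/px.
#' @param min_prominence_frac peak prominence threshold as a fraction of the
#'   profile range.
#' @param min_separation_um minimum peak separation in um.
#' @return sarcomere length in um with attribute `in_physiological_range`,
#'   or `NA` (with `reason`) when fewer than 3 bands are detected.
#' @export
sarcomere_length <- function(section, pixel_size_um,
                             min_prominence_frac = 0.1,
                             min_separation_um = 1.5) {
  stopifnot(pixel_size_um > 0)
  if (is.null(dim(section)) || any(dim(section) < 8))
    stop("invalid input: section must be at least 8x8 px")
  ang <- orientation_deg(section)
  if (is.finite(ang) && abs(ang) > 1) {
    rot <- EBImage::rotate(EBImage::Image(section), ang)
    section <- EBImage::imageData(rot)
  }
  prof <- colMeans(section)
  rng <- diff(range(prof))
  if (rng <= .Machine$double.eps)
    return(undefined_result("no striation bands detected"))
  ## absolute prominence floor: bands must clear the profile's pixel-scale
  ## noise (residual from a short running median, which preserves the
  ## micron-scale striation), otherwise a flat noisy myotube would yield
  ## spurious "peaks" at random spacings
  noise_floor <- 1.4826 * mad(prof - runmed(prof, 5))
  peaks <- find_profile_peaks(prof,
                              min_prom = max(min_prominence_frac * rng,
                                             6 * noise_floor),
                              min_sep = min_separation_um / pixel_size_um)
  if (length(peaks) < 3)
    return(undefined_result("fewer than 3 striation bands detected"))
  ## 3-point parabolic sub-pixel refinement
  refine <- vapply(peaks, function(i) {
    if (i <= 1 || i >= length(prof)) return(as.numeric(i))
    y0 <- prof[i - 1]; y1 <- prof[i]; y2 <- prof[i + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < .Machine$double.eps) return(as.numeric(i))
    i + 0.5 * (y0 - y2) / den
  }, numeric(1))
  len <- median(diff(sort(refine))) * pixel_size_um
  structure(len, in_physiological_range = len >= 1.8 && len <= 2.4)
}

## Fiber orientation (degrees from horizontal) via intensity second moments.
orientation_deg <- function(section) {
  w <- section - min(section)
  s <- sum(w)
  if (s <= 0) return(0)
  r <- row(section); c <- col(section)
  mr <- sum(w * r) / s; mc <- sum(w * c) / s
  mu20 <- sum(w * (c - mc)^2) / s
  mu02 <- sum(w * (r - mr)^2) / s
  mu11 <- sum(w * (c - mc) * (r - mr)) / s
  if (abs(mu20 - mu02) < 1e-12 && abs(mu11) < 1e-12) return(0)
  0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
}

## Peak detection with prominence and separation constraints.
find_profile_peaks <- function(y, min_prom, min_sep) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    lv <- y[seq_len(i - 1)]
    rv <- y[seq(i + 1, n)]
    hl <- which(lv > y[i]); hr <- which(rv > y[i])
    lmin <- if (length(hl)) min(y[(max(hl) + 1):(i - 1)]) else min(lv)
    rmin <- if (length(hr)) min(y[(i + 1):(i + min(hr) - 1)]) else min(rv)
    y[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= min_prom]
  if (length(cand) <= 1) return(cand)
  ## greedy: keep highest peaks subject to separation
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

#' Crop myotube sections from the alpha-actinin channel
#'
#' Selects up to `n` myotube objects from the Otsu mask of the actinin
#' channel (largest first) and crops a section of the given width centered
#' on each object, spanning the full field along the fiber axis. Used to
#' feed [radial_power_spectrum()] and [sarcomere_length()] without manual
#' region selection.
#'
#' @param fov an [fov] with an `actinin` channel.
#' @param n number of sections.
#' @param width_um section width across the fiber in um.
#' @return list of 2D matrices (possibly fewer than `n`).
#' @export
crop_myotube_sections <- function(fov, n = 5, width_um = 50) {
  stopifnot(inherits(fov, "fov"), "actinin" %in% names(fov$channels))
  act <- fov$channels$actinin
  px <- fov$pixel_size_um
  mask <- actinin_mask(act, px)
  if (!any(mask)) return(list())
  lc <- label_components(mask)
  if (length(lc$areas_px) == 0) return(list())
  ord <- order(lc$areas_px, decreasing = TRUE)
  w_px <- round(width_um / px)
  out <- list()
  for (obj in head(ord, n)) {
    rows <- which(rowSums(lc$labels == obj) > 0)
    ctr <- round(mean(range(rows)))
    half <- min(w_px %/% 2, (diff(range(rows)) + 1) %/% 2)
    r0 <- max(1, ctr - half); r1 <- min(nrow(act), ctr + half)
    if (r1 - r0 + 1 >= 8) out[[length(out) + 1]] <- act[r0:r1, , drop = FALSE]
  }
  out
}

#' All muscle-structure metrics for one field of view
#'
#' Convenience wrapper computing nuclei density, myogenic index, myotube
#' width, and — from automatically cropped myotube sections — the mean
#' sarcomere index and median sarcomere length.
#'
#' @param fov an [fov] with `actinin` and `dapi` channels.
#' @param n_sections number of myotube sections for the sarcomere metrics.
#' @param seed optional seed for the random sub-field sampling in
#'   [myotube_width()].
#' @param ... passed to [count_nuclei()] / [myogenic_index()].
#' @return object of class `tissue_structure_metrics` with fields
#'   `nuclei_per_mm2`, `myogenic_index`, `myotube_width_um`,
#'   `sarcomere_index`, `sarcomere_length_um`, `sarcomere_length_in_range`.
#' @export
tissue_structure_metrics <- function(fov, n_sections = 5, seed = NULL, ...) {
  secs <- crop_myotube_sections(fov, n = n_sections)
  idx <- NA_real_; len <- NA_real_; in_range <- NA
  if (length(secs) > 0) {
    idx <- mean(vapply(secs, function(s)
      sarcomere_index(radial_power_spectrum(s, fov$pixel_size_um))$sarcomere_index,
      numeric(1)))
    lens <- vapply(secs, function(s)
      as.numeric(sarcomere_length(s, fov$pixel_size_um)), numeric(1))
    if (any(!is.na(lens))) {
      len <- median(lens, na.rm = TRUE)
      in_range <- len >= 1.8 && len <= 2.4
    }
  }
  structure(list(nuclei_per_mm2 = count_nuclei(fov, ...),
                 myogenic_index = myogenic_index(fov, ...),
                 myotube_width_um = myotube_width(fov, seed = seed),
                 sarcomere_index = idx,
                 sarcomere_length_um = len,
                 sarcomere_length_in_range = in_range),
            class = "tissue_structure_metrics")
}

#' @export
print.tissue_structure_metrics <- function(x, ...) {
  cat(sprintf(paste0("<tissue_structure_metrics> %.0f nuclei/mm^2 | myogenic %.2f | ",
                     "width %.1f um | sarc index %.2f | sarc length %.2f um%s\n"),
              x$nuclei_per_mm2, x$myogenic_index, x$myotube_width_um,
              x$sarcomere_index, x$sarcomere_length_um,
              if (isTRUE(x$sarcomere_length_in_range)) " (in range)" else ""))
  invisible(x)
}
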