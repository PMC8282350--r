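#' Prescribed stress waveform for the MTF video generator
#'
#' Piecewise waveform mirroring an MTF pacing protocol: a rest span at basal
#' stress, a 2 Hz pacing span where each cycle carries one raised-cosine
#' twitch pulse returning to basal, and a 20 Hz span modeled as a ramp to a
#' fused tetanus plateau. Requires
#' `tetanus_plateau_kpa >= twitch_peak_kpa >= basal_kpa`.
#'
#' @param basal_kpa baseline stress in kPa.
#' @param twitch_peak_kpa per-cycle peak stress during pacing.
#' @param twitch_rate_hz pacing rate (Hz).
#' @param tetanus_plateau_kpa plateau stress during high-rate stimulation.
#' @param schedule data frame with columns `mode` (`rest`/`twitch`/`tetanus`)
#'   and `duration_s`, in order.
#' @param twitch_pulse_s duration of each twitch pulse within its cycle (s).
#' @param tetanus_ramp_s rise time to the tetanus plateau (s).
#' @return object of class `stress_waveform`.
#' @export
stress_waveform <- function(basal_kpa = 10, twitch_peak_kpa = 25,
                            twitch_rate_hz = 2, tetanus_plateau_kpa = 100,
                            schedule = data.frame(
                              mode = c("rest", "twitch", "tetanus"),
                              duration_s = c(0.5, 4, 1.25)),
                            twitch_pulse_s = 0.15,
                            tetanus_ramp_s = 0.25) {
  stopifnot(basal_kpa >= 0, twitch_peak_kpa >= basal_kpa,
            tetanus_plateau_kpa >= twitch_peak_kpa, twitch_rate_hz > 0,
            all(schedule$mode %in% c("rest", "twitch", "tetanus")),
            all(schedule$duration_s > 0),
            twitch_pulse_s < 1 / twitch_rate_hz)
  structure(as.list(environment()), class = "stress_waveform")
}

#' Evaluate a stress waveform at given times
#'
#' @param wave a [stress_waveform()].
#' @param t times in seconds (vectorized), from the start of the schedule.
#' @return stress in kPa at each time.
#' @export
waveform_stress <- function(wave, t) {
  stopifnot(inherits(wave, "stress_waveform"))
  ends <- cumsum(wave$schedule$duration_s)
  starts <- c(0, head(ends, -1))
  sigma <- rep(wave$basal_kpa, length(t))
  for (i in seq_len(nrow(wave$schedule))) {
    sel <- t >= starts[i] & t < ends[i]
    if (!any(sel)) next
    u <- t[sel] - starts[i]
    sigma[sel] <- switch(
      wave$schedule$mode[i],
      rest = wave$basal_kpa,
      twitch = {
        phase <- u %% (1 / wave$twitch_rate_hz)
        pulse <- ifelse(phase < wave$twitch_pulse_s,
                        sin(pi * phase / wave$twitch_pulse_s)^2, 0)
        wave$basal_kpa + (wave$twitch_peak_kpa - wave$basal_kpa) * pulse
      },
      tetanus = {
        ramp <- pmin(u / wave$tetanus_ramp_s, 1)
        rise <- 0.5 * (1 - cos(pi * ramp))
        wave$basal_kpa + (wave$tetanus_plateau_kpa - wave$basal_kpa) * rise
      })
  }
  sigma[t >= ends[length(ends)]] <- wave$basal_kpa
  sigma
}

## Alias so mtf_video_spec() can take a default waveform without its
## argument name shadowing the constructor.
default_stress_waveform <- function() stress_waveform()

#' Specification of a synthetic MTF top-view video
#'
#' Film dimensions and arrangement default to the assay layout: cantilevers
#' of 3.4 x 1.4 mm separated by 0.8 mm, up to two rows of four, recorded at
#' 100 frames per second.
#'
#' @param film_length_mm,film_width_mm,film_gap_mm cantilever geometry (mm).
#' @param n_films number of cantilevers (laid out in rows of four).
#' @param fps frame rate (frames per second).
#' @param stress_waveform a [stress_waveform()] driving every film (`NULL`
#'   uses the default waveform).
#' @param pixel_size_mm rendered pixel size (mm/px).
#' @param margin_mm background margin around the film array (mm).
#' @return object of class `mtf_video_spec`.
#' @export
mtf_video_spec <- function(film_length_mm = 3.4, film_width_mm = 1.4,
                           film_gap_mm = 0.8, n_films = 8, fps = 100,
                           stress_waveform = NULL,
                           pixel_size_mm = 0.02, margin_mm = 0.2) {
  if (is.null(stress_waveform)) stress_waveform <- default_stress_waveform()
  stopifnot(film_length_mm > 0, film_width_mm > 0, film_gap_mm > 0,
            n_films >= 1, fps > 0, pixel_size_mm > 0,
            inherits(stress_waveform, "stress_waveform"))
  structure(as.list(environment()), class = "mtf_video_spec")
}

#' Render a synthetic MTF video from a prescribed stress waveform
#'
#' For each frame time, the waveform stress is mapped to a radius of
#' curvature through the inverse Stoney relation ([radius_from_stress()]),
#' the radius to a bend angle `theta = L/R`, and the bend angle to a
#' projected film length through the constant-curvature projection law.
#' Each film is rendered as a dark rectangle of that projected length (base
#' anchored, tip anti-aliased with exact partial-pixel coverage) on a light
#' background. Stresses implying `theta > pi` are refused: past a half-turn
#' the curled film overlaps its own base and the projection law is no longer
#' measurable.
#'
#' @param spec an [mtf_video_spec()].
#' @param geometry an [mtf_geometry()].
#' @param seed integer RNG seed (the default renderer is noise-free but the
#'   seed is recorded in the truth sidecar).
#' @param noise_sd optional additive Gaussian noise SD on frames.
#' @return list with `frames` (array `ny x nx x n_frames`, intensities in
#'   `[0, 1]`), `meta` (fps, pixel size, per-film ROIs, schedule, geometry)
#'   and `truth` (per-frame stress and rendered projected length per film).
#' @export
make_mtf_video <- function(spec, geometry = mtf_geometry(), seed = 1,
                           noise_sd = 0) {
  stopifnot(inherits(spec, "mtf_video_spec"), inherits(geometry, "mtf_geometry"))
  wave <- spec$stress_waveform
  p <- spec$pixel_size_mm
  L <- spec$film_length_mm
  n_films <- spec$n_films
  per_row <- min(4L, n_films)
  n_cols <- ceiling(n_films / per_row)

  total_t <- sum(wave$schedule$duration_s)
  n_frames <- floor(total_t * spec$fps)
  t <- (seq_len(n_frames) - 1) / spec$fps
  sigma <- waveform_stress(wave, t)

  R <- radius_from_stress(sigma, geometry)
  theta <- L / R
  if (any(theta > pi))
    stop("unsupported curl: stress implies a bend angle beyond pi")
  x_proj <- projected_length_from_theta(theta, L)

  ## Layout (pixel-snapped): films point +x from their base column.
  w_px <- round(spec$film_width_mm / p)
  L_px <- L / p
  gap_px <- round(spec$film_gap_mm / p)
  mar_px <- round(spec$margin_mm / p)
  nx <- 2 * mar_px + n_cols * ceiling(L_px) + (n_cols - 1) * gap_px
  ny <- 2 * mar_px + per_row * w_px + (per_row - 1) * gap_px

  rois <- vector("list", n_films)
  for (i in seq_len(n_films)) {
    cx <- (i - 1) %/% per_row    # column in the array
    cy <- (i - 1) %% per_row     # row in the array
    x0 <- mar_px + cx * (ceiling(L_px) + gap_px) + 1L
    y0 <- mar_px + cy * (w_px + gap_px) + 1L
    rois[[i]] <- list(x0 = x0, x1 = x0 + ceiling(L_px) - 1L,
                      y0 = y0, y1 = y0 + w_px - 1L, base = "left")
  }

  light <- 1; dark <- 0.1
  frames <- array(light, dim = c(ny, nx, n_frames))
  lengths_mm <- matrix(x_proj, n_frames, n_films)  # same waveform per film

  with_rng_seed(seed, {
    for (k in seq_len(n_frames)) {
      len_px <- x_proj[k] / p
      full <- floor(len_px)
      frac <- len_px - full
      for (i in seq_len(n_films)) {
        r <- rois[[i]]
        rows <- r$y0:r$y1
        if (full > 0)
          frames[rows, r$x0:(r$x0 + full - 1L), k] <- dark
        if (frac > 0 && r$x0 + full <= nx)
          frames[rows, r$x0 + full, k] <- light * (1 - frac) + dark * frac
      }
      if (noise_sd > 0)
        frames[, , k] <- clip(frames[, , k] +
                                rnorm(ny * nx, 0, noise_sd), 0, 1)
    }
  })

  meta <- list(fps = spec$fps, pixel_size_mm = p, rois = rois,
               film_length_mm = L, schedule = wave$schedule,
               twitch_rate_hz = wave$twitch_rate_hz, geometry = geometry)
  truth <- synthetic_truth(
    "mtf_video",
    params = list(basal_kpa = wave$basal_kpa,
                  twitch_peak_kpa = wave$twitch_peak_kpa,
                  tetanus_plateau_kpa = wave$tetanus_plateau_kpa,
                  twitch_rate_hz = wave$twitch_rate_hz,
                  fps = spec$fps, pixel_size_mm = p,
                  n_films = n_films,
                  time_s = t, stress_kpa = sigma,
                  projected_length_mm = x_proj,
                  noise_sd = noise_sd),
    seed = seed)
  list(frames = frames, meta = meta, truth = truth)
}
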