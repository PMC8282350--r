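#' Muscular thin film geometry
#'
#' Geometric and elastic parameters needed to convert film curvature into
#' tissue stress. Defaults for the hydrogel substrate follow the measured
#' values for the micromolded gelatin films used with this assay
#' (thickness 91.3 um, elastic modulus 108.3 kPa); the effective tissue
#' thickness is not directly measurable in the assay and must be reviewed
#' per experiment. `stoney_correction` is a multiplicative hook for
#' modified-Stoney variants (default 1, the classic plate form).
#'
#' @param film_length_mm cantilever length in mm.
#' @param gel_thickness_um substrate (hydrogel) thickness in um.
#' @param gel_modulus_kpa substrate elastic modulus in kPa.
#' @param poisson_ratio substrate Poisson ratio in `[0, 0.5]`.
#' @param tissue_thickness_um effective muscle layer thickness in um.
#' @param stoney_correction multiplicative correction factor.
#' @return object of class `mtf_geometry`.
#' @export
mtf_geometry <- function(film_length_mm = 3.4,
                         gel_thickness_um = 91.3,
                         gel_modulus_kpa = 108.3,
                         poisson_ratio = 0.5,
                         tissue_thickness_um = 15,
                         stoney_correction = 1) {
  stopifnot(film_length_mm > 0, gel_thickness_um > 0, gel_modulus_kpa > 0,
            poisson_ratio >= 0, poisson_ratio <= 0.5,
            tissue_thickness_um > 0, stoney_correction > 0)
  structure(as.list(environment()), class = "mtf_geometry")
}

#' Stoney-type conversion between film curvature and tissue stress
#'
#' `stoney_stress` maps a radius of curvature to the contractile stress the
#' tissue layer exerts on the substrate,
#' `sigma = k * E_gel * t_gel^2 / (6 * (1 - nu) * t_tissue * R)`,
#' with `k` the configurable correction factor; a flat film (infinite
#' radius) maps to 0 kPa. `radius_from_stress` is the exact inverse used by
#' the video generator.
#'
#' @param radius_mm radius of curvature in mm (`Inf` = flat film). Vectorized.
#' @param geom an [mtf_geometry()].
#' @return stress in kPa (`stoney_stress`) or radius in mm
#'   (`radius_from_stress`).
#' @examples
#' g <- mtf_geometry()
#' stoney_stress(2, g)  # 108.3 * 0.0913^2 / (6 * 0.5 * 0.015 * 2) = 10.03 kPa
#' @export
stoney_stress <- function(radius_mm, geom) {
  stopifnot(inherits(geom, "mtf_geometry"))
  if (any(radius_mm <= 0, na.rm = TRUE))
    stop("invalid input: radius must be positive (use Inf for a flat film)")
  k <- geom$stoney_correction * geom$gel_modulus_kpa *
    (geom$gel_thickness_um / 1000)^2 /
    (6 * (1 - geom$poisson_ratio) * (geom$tissue_thickness_um / 1000))
  ifelse(is.infinite(radius_mm), 0, k / radius_mm)
}

#' @rdname stoney_stress
#' @param stress_kpa tissue stress in kPa (0 maps to `Inf`, a flat film).
#' @export
radius_from_stress <- function(stress_kpa, geom) {
  stopifnot(inherits(geom, "mtf_geometry"))
  if (any(stress_kpa < 0, na.rm = TRUE))
    stop("invalid input: stress must be nonnegative")
  k <- geom$stoney_correction * geom$gel_modulus_kpa *
    (geom$gel_thickness_um / 1000)^2 /
    (6 * (1 - geom$poisson_ratio) * (geom$tissue_thickness_um / 1000))
  ifelse(stress_kpa == 0, Inf, k / stress_kpa)
}

#' Invert the top-view projection of a constant-curvature film
#'
#' A film of length `L` bent at constant curvature `1/R` through the bend
#' angle `theta = L / R` projects, viewed from above, to
#' `x = L * sin(theta) / theta` while `theta <= pi/2`, and to `x = R` once
#' the tip has curled past vertical (`pi/2 < theta <= pi`). This function
#' inverts that law piecewise: for `x/L > 2/pi` it solves
#' `sin(theta)/theta = x/L` by bisection (tolerance 1e-9); for
#' `x/L <= 2/pi` the projection equals the radius directly. `x = L` returns
#' `Inf`, the flat-film sentinel.
#'
#' @param x_mm projected film length in mm (vectorized).
#' @param L_mm film length in mm.
#' @return radius of curvature in mm (`Inf` for a flat film).
#' @export
curvature_from_projection <- function(x_mm, L_mm) {
  stopifnot(L_mm > 0)
  ## tolerate tip-rounding overshoot of < 0.1% before declaring invalid
  x_mm <- ifelse(x_mm > L_mm & x_mm <= L_mm * 1.001, L_mm, x_mm)
  if (any(x_mm <= 0 | x_mm > L_mm, na.rm = TRUE))
    stop("invalid input: projected length must lie in (0, film length]")
  vapply(x_mm, function(x) {
    if (is.na(x)) return(NA_real_)
    u <- x / L_mm
    if (u == 1) return(Inf)
    if (u <= 2 / pi) return(x)          # curled past vertical: projection = R
    lo <- 1e-12; hi <- pi / 2           # sin(t)/t decreasing on (0, pi/2]
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (sin(mid) / mid > u) lo <- mid else hi <- mid
    }
    L_mm / ((lo + hi) / 2)
  }, numeric(1))
}

## Forward projection law used by the generator: theta in [0, pi].
projected_length_from_theta <- function(theta, L_mm) {
  stopifnot(all(theta >= 0), all(theta <= pi))
  ifelse(theta < 1e-9, L_mm,
         ifelse(theta <= pi / 2, L_mm * sin(theta) / theta, L_mm / theta))
}

#' Summarize basal, twitch and tetanus stress from a paced stress trace
#'
#' Basal stress is the minimum stress observed during the 2 Hz pacing span;
#' twitch stress is the mean of the per-cycle stress maxima over the paced
#' contraction cycles (cycles delimited by the stimulus grid, nominally 8
#' cycles at 2 Hz); tetanus stress is the mean stress over a 1 s window at
#' the end of the 20 Hz span; the tetanus-to-twitch ratio divides the two.
#' Ratios outside the in-situ physiological range `[4, 10]` and ordering
#' violations (`tetanus >= twitch >= basal`) are flagged, never corrected.
#'
#' @param stress_kpa numeric stress series in kPa.
#' @param time_s sample times in s (same length).
#' @param schedule data frame with columns `mode` (`"rest"`, `"twitch"`,
#'   `"tetanus"`) and `duration_s`, in recording order.
#' @param twitch_rate_hz pacing rate of the twitch span (Hz).
#' @param n_cycles nominal number of paced cycles averaged for twitch stress.
#' @param tetanus_window_s length of the tetanus averaging window (s).
#' @return object of class `contraction_summary` with fields `basal_kpa`,
#'   `twitch_kpa`, `tetanus_kpa`, `tetanus_to_twitch`, `in_physiological_range`
#'   and a character vector of `flags`.
#' @export
summarize_contractions <- function(stress_kpa, time_s, schedule,
                                   twitch_rate_hz = 2, n_cycles = 8,
                                   tetanus_window_s = 1) {
  stopifnot(length(stress_kpa) == length(time_s),
            all(c("mode", "duration_s") %in% names(schedule)))
  flags <- character(0)
  ends <- cumsum(schedule$duration_s)
  starts <- c(0, head(ends, -1))
  span <- function(mode) {
    i <- which(schedule$mode == mode)[1]
    if (is.na(i)) return(NULL)
    c(starts[i], ends[i])
  }

  tw <- span("twitch")
  if (is.null(tw)) stop("schedule contains no twitch span")
  in_tw <- time_s >= tw[1] & time_s < tw[2]
  basal <- min(stress_kpa[in_tw])

  ## Cycles delimited by the stimulus grid.
  cycle_T <- 1 / twitch_rate_hz
  n_avail <- floor((tw[2] - tw[1]) / cycle_T)
  if (n_avail < n_cycles) {
    flags <- c(flags, sprintf("only %d complete twitch cycles (expected %d)",
                              n_avail, n_cycles))
  }
  n_use <- min(n_avail, n_cycles)
  if (n_use < 1) stop("twitch span shorter than one pacing cycle")
  peaks <- vapply(seq_len(n_use), function(k) {
    t0 <- tw[1] + (k - 1) * cycle_T
    max(stress_kpa[time_s >= t0 & time_s < t0 + cycle_T])
  }, numeric(1))
  twitch <- mean(peaks)

  te <- span("tetanus")
  if (is.null(te)) stop("schedule contains no tetanus span")
  w0 <- max(te[1], te[2] - tetanus_window_s)
  if (te[2] - te[1] < tetanus_window_s)
    flags <- c(flags, "tetanus span shorter than the averaging window")
  in_te <- time_s >= w0 & time_s < te[2]
  tetanus <- mean(stress_kpa[in_te])

  if (!(tetanus >= twitch && twitch >= basal))
    flags <- c(flags, "ordering violation: expected tetanus >= twitch >= basal")
  ratio <- if (twitch > 0) tetanus / twitch else NA_real_
  in_range <- !is.na(ratio) && ratio >= 4 && ratio <= 10
  if (!is.na(ratio) && !in_range)
    flags <- c(flags, sprintf("tetanus-to-twitch ratio %.2f outside the in-situ range [4, 10]",
                              ratio))

  structure(list(basal_kpa = basal, twitch_kpa = twitch, tetanus_kpa = tetanus,
                 tetanus_to_twitch = ratio,
                 in_physiological_range = in_range, flags = flags),
            class = "contraction_summary")
}

#' @export
print.contraction_summary <- function(x, ...) {
  cat(sprintf("<contraction_summary> basal %.2f | twitch %.2f | tetanus %.2f kPa | ratio %.2f%s\n",
              x$basal_kpa, x$twitch_kpa, x$tetanus_kpa, x$tetanus_to_twitch,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}
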