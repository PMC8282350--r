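test_that("projection inversion: closed forms, sentinel, self-consistency", {
  L <- 3.4
  expect_identical(curvature_from_projection(L, L), Inf)

  ## piecewise boundary: x/L = 2/pi -> theta = pi/2, R = 2L/pi
  expect_equal(curvature_from_projection(L * 2 / pi, L), 2 * L / pi,
               tolerance = 1e-6)

  ## bisection root satisfies sin(theta)/theta = x/L to 1e-9
  R <- curvature_from_projection(0.9 * L, L)
  theta <- L / R
  expect_lt(abs(sin(theta) / theta - 0.9), 1e-9)

  ## curled-past-vertical branch: projection equals the radius
  expect_equal(curvature_from_projection(0.5 * L, L), 0.5 * L)

  expect_error(curvature_from_projection(0, L), "invalid input")
  expect_error(curvature_from_projection(1.1 * L, L), "invalid input")
})

test_that("stoney conversion: hand-computed value, proportionality, sentinel", {
  g <- mtf_geometry()  # E = 108.3 kPa, t_gel = 91.3 um, nu = 0.5, t_t = 15 um
  ## hand evaluation: 108.3 * 0.0913^2 / (6 * 0.5 * 0.015 * 2) kPa
  expect_equal(stoney_stress(2, g), 10.0306, tolerance = 1e-4)
  expect_equal(stoney_stress(1, g), 2 * stoney_stress(2, g))
  expect_equal(stoney_stress(Inf, g), 0)
  expect_equal(radius_from_stress(stoney_stress(2, g), g), 2)
  expect_error(mtf_geometry(gel_thickness_um = -1))
  expect_error(stoney_stress(-2, g), "invalid input")
})

test_that("stress from projection is monotone decreasing in projected length", {
  g <- small_mtf_geometry()
  x <- seq(0.4, 3.39, length.out = 60)
  sig <- stoney_stress(curvature_from_projection(x, 3.4), g)
  expect_true(all(diff(sig) < 0))
})

test_that("contraction summaries: constant trace, flags, schedule handling", {
  sched <- data.frame(mode = c("rest", "twitch", "tetanus"),
                      duration_s = c(0.5, 4, 1.25))
  t <- seq(0, 5.74, by = 0.01)
  s <- summarize_contractions(rep(7, length(t)), t, sched)
  expect_equal(s$basal_kpa, 7)
  expect_equal(s$twitch_kpa, 7)
  expect_equal(s$tetanus_kpa, 7)
  expect_equal(s$tetanus_to_twitch, 1)
  expect_false(s$in_physiological_range)
  expect_true(any(grepl("outside the in-situ range", s$flags)))

  ## ratio 4 within [4, 10]; ratio 12 supraphysiological
  wave <- stress_waveform()
  sig <- waveform_stress(wave, t)
  s4 <- summarize_contractions(sig, t, sched)
  ## 100 Hz sampling lands 5 ms off the pulse peak: ~1% twitch shortfall
  expect_equal(s4$tetanus_to_twitch, 4, tolerance = 0.03)
  expect_true(s4$in_physiological_range)
  ## twitch peaks 25, tetanus 300: ratio ~12, supraphysiological
  sig12 <- waveform_stress(stress_waveform(twitch_peak_kpa = 25,
                                           tetanus_plateau_kpa = 300), t)
  s12 <- summarize_contractions(sig12, t, sched)
  expect_gt(s12$tetanus_to_twitch, 10)
  expect_false(s12$in_physiological_range)

  ## fewer than 8 cycles: flagged, computed over available cycles
  sched_short <- data.frame(mode = c("rest", "twitch", "tetanus"),
                            duration_s = c(0.5, 2, 1.25))
  t2 <- seq(0, 3.74, by = 0.01)
  s2 <- summarize_contractions(waveform_stress(wave, t2), t2, sched_short)
  expect_true(any(grepl("complete twitch cycles", s2$flags)))
  expect_equal(s2$twitch_kpa, 25, tolerance = 0.02)
})

test_that("video round trip recovers the prescribed waveform within 2%", {
  v <- small_mtf_video(seed = 2, n_films = 1, pixel_size_mm = 0.04)
  res <- analyze_mtf(v)

  ## tracked lengths match the rendered truth within one pixel
  expect_lt(max(abs(res$lengths_mm[, 1] -
                      v$truth$params$projected_length_mm)), 0.04 + 1e-9)
  expect_false(any(attr(res$lengths_mm, "quality_fail")))

  s <- res$summaries[[1]]
  expect_lt(abs(s$basal_kpa - 10) / 10, 0.02)
  expect_lt(abs(s$twitch_kpa - 25) / 25, 0.02)
  expect_lt(abs(s$tetanus_kpa - 100) / 100, 0.02)
  expect_lt(abs(s$tetanus_to_twitch - 4) / 4, 0.02)
  expect_true(s$in_physiological_range)
})

test_that("summaries are invariant to frame-rate doubling", {
  wave <- stress_waveform(schedule = data.frame(
    mode = c("rest", "twitch", "tetanus"), duration_s = c(0.2, 2, 1.25)))
  g <- small_mtf_geometry()
  v1 <- make_mtf_video(mtf_video_spec(n_films = 1, pixel_size_mm = 0.04,
                                      stress_waveform = wave, fps = 100),
                       g, seed = 1)
  v2 <- make_mtf_video(mtf_video_spec(n_films = 1, pixel_size_mm = 0.04,
                                      stress_waveform = wave, fps = 200),
                       g, seed = 1)
  s1 <- analyze_mtf(v1)$summaries[[1]]
  s2 <- analyze_mtf(v2)$summaries[[1]]
  expect_lt(abs(s1$basal_kpa - s2$basal_kpa) / s1$basal_kpa, 0.02)
  expect_lt(abs(s1$twitch_kpa - s2$twitch_kpa) / s1$twitch_kpa, 0.02)
  expect_lt(abs(s1$tetanus_kpa - s2$tetanus_kpa) / s1$tetanus_kpa, 0.02)
})
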