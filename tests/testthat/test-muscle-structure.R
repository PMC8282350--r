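test_that("nuclei counting recovers the programmed density and is scale-invariant", {
  spec <- structure_image_spec(field_size_um = c(600, 600), pixel_size_um = 0.3,
                               n_myotubes = 6, n_nuclei = 150,
                               fraction_nuclei_in_myotubes = 0.5,
                               noise_sd = 0.02)
  g <- make_structure_image(spec, seed = 3)
  est <- count_nuclei(g$fov)
  expect_lt(abs(est - g$truth$params$nuclei_per_mm2) /
              g$truth$params$nuclei_per_mm2, 0.02)

  ## uniform intensity scaling leaves the count unchanged
  f2 <- g$fov
  f2$channels$dapi <- f2$channels$dapi * 2
  expect_equal(count_nuclei(f2), est)

  ## blank channel: zero with a warning
  blank <- fov(list(dapi = matrix(0, 50, 50)), 0.5)
  expect_warning(n0 <- count_nuclei(blank), "empty or constant")
  expect_equal(n0, 0)
})

test_that("myogenic index recovers the programmed nuclear fraction", {
  spec <- structure_image_spec(field_size_um = c(600, 600), pixel_size_um = 0.3,
                               n_myotubes = 6, n_nuclei = 150,
                               fraction_nuclei_in_myotubes = 0.5,
                               noise_sd = 0.02)
  g <- make_structure_image(spec, seed = 3)
  expect_lt(abs(myogenic_index(g$fov) - 0.5), 0.05)

  ## all nuclei inside: index 1
  s1 <- structure_image_spec(field_size_um = c(300, 300), pixel_size_um = 0.3,
                             n_myotubes = 3, myotube_width_um = 40,
                             n_nuclei = 40, fraction_nuclei_in_myotubes = 1,
                             noise_sd = 0.02)
  g1 <- make_structure_image(s1, seed = 2)
  expect_equal(as.numeric(myogenic_index(g1$fov)), 1)

  ## empty actinin with nuclei present: 0, not undefined
  f <- g1$fov
  f$channels$actinin <- matrix(0, nrow(f$channels$dapi), ncol(f$channels$dapi))
  expect_equal(as.numeric(myogenic_index(f)), 0)

  ## zero nuclei: undefined, not 0
  f2 <- g1$fov
  f2$channels$dapi <- matrix(0, nrow(f2$channels$dapi), ncol(f2$channels$dapi))
  r <- myogenic_index(f2)
  expect_true(is_undefined(r))
  expect_match(attr(r, "reason"), "zero nuclei")
})

test_that("myotube width recovers programmed widths and is rotation-invariant", {
  s1 <- structure_image_spec(field_size_um = c(200, 200), pixel_size_um = 0.2,
                             n_myotubes = 1, myotube_width_um = 20,
                             n_nuclei = 0, noise_sd = 0.02)
  g1 <- make_structure_image(s1, seed = 4)
  w1 <- myotube_width(g1$fov, seed = 1)
  expect_lt(abs(w1 - 20), 1)

  s2 <- structure_image_spec(field_size_um = c(200, 200), pixel_size_um = 0.2,
                             n_myotubes = 2, myotube_width_um = c(10, 30),
                             n_nuclei = 0, noise_sd = 0.02)
  g2 <- make_structure_image(s2, seed = 4)
  w2 <- myotube_width(g2$fov, seed = 2)
  expect_lt(abs(w2 - 20), 1)

  ## 90 degree rotation changes nothing
  rot <- fov(list(actinin = t(g2$fov$channels$actinin)), 0.2)
  expect_lt(abs(myotube_width(rot, seed = 2) - w2), 0.5)

  ## no objects: undefined
  empty <- fov(list(actinin = matrix(0, 64, 64)), 0.5)
  expect_true(is_undefined(myotube_width(empty, seed = 1)))
})

test_that("radial power spectrum is unit-integral with the right fundamental", {
  sec <- striated_section(spacing_um = 2, contrast = 0.8, noise_sd = 0.05)
  p <- radial_power_spectrum(sec, 0.1)
  expect_lt(abs(pracma::trapz(p$frequency_per_um, p$power) - 1), 1e-6)
  expect_true(all(diff(p$frequency_per_um) > 0))
  expect_gt(min(p$frequency_per_um), 0)  # DC excluded

  df <- median(diff(p$frequency_per_um))
  f_peak <- p$frequency_per_um[which.max(p$power)]
  expect_lt(abs(f_peak - 0.5), df + 1e-9)

  ## white noise: no local maximum more than 3x an exponential baseline
  set.seed(11)
  wn <- matrix(rnorm(128 * 128), 128)
  pw <- radial_power_spectrum(wn, 0.2)
  co <- coef(lm(log(pmax(pw$power, 1e-12)) ~ pw$frequency_per_um))
  basel <- exp(co[1]) * exp(co[2] * pw$frequency_per_um)
  peaks_i <- which(diff(sign(diff(pw$power))) == -2) + 1
  expect_true(all(pw$power[peaks_i] < 3 * basel[peaks_i]))

  expect_error(radial_power_spectrum(matrix(0, 4, 4), 0.1), "8x8")
})

test_that("sarcomere index separates striated from unstriated myotubes", {
  ## exactly aperiodic profile: index ~ 0
  f <- seq(0.01, 2.5, by = 0.01)
  y <- 3 * exp(-2 * f)
  y <- y / pracma::trapz(f, y)
  pr <- structure(list(frequency_per_um = f, power = y),
                  class = "power_spectrum_profile")
  fit0 <- sarcomere_index(pr)
  expect_lt(fit0$sarcomere_index, 1e-3)

  ## zero-contrast synthetic image: index below 0.05
  sec0 <- striated_section(contrast = 0, noise_sd = 0.05, seed = 2)
  p0 <- radial_power_spectrum(sec0, 0.1)
  expect_lt(sarcomere_index(p0)$sarcomere_index, 0.05)

  ## monotone non-decreasing in contrast at fixed noise
  idx <- vapply(c(0, 0.2, 0.4, 0.8), function(ct) {
    sec <- striated_section(contrast = ct, noise_sd = 0.05, seed = 5)
    sarcomere_index(radial_power_spectrum(sec, 0.1))$sarcomere_index
  }, numeric(1))
  expect_true(all(diff(idx) >= -0.02))
  expect_true(all(idx >= 0 & idx <= 1))

  ## Gaussian centers exclude DC
  sec <- striated_section(contrast = 0.8, noise_sd = 0.05)
  fit <- sarcomere_index(radial_power_spectrum(sec, 0.1))
  expect_true(all(fit$gaussian_components$center_per_um > 0))
})

test_that("sarcomere length recovers programmed spacings and flags range", {
  sec <- striated_section(spacing_um = 2, contrast = 0.8, noise_sd = 0.05)
  len <- sarcomere_length(sec, 0.1)
  expect_lt(abs(as.numeric(len) - 2), 0.05)
  expect_true(attr(len, "in_physiological_range"))

  sec22 <- striated_section(spacing_um = 2.2, contrast = 0.8,
                            noise_sd = 0.05, pixel_size_um = 0.11)
  len22 <- sarcomere_length(sec22, 0.11)
  expect_lt(abs(as.numeric(len22) - 2.2), 0.06)
  expect_true(attr(len22, "in_physiological_range"))

  ## unstriated: undefined, mirroring unanalyzable myotubes
  sec0 <- striated_section(contrast = 0, noise_sd = 0.05, seed = 3)
  r <- sarcomere_length(sec0, 0.1)
  expect_true(is_undefined(r))
  expect_match(attr(r, "reason"), "bands")

  ## out-of-range spacing is flagged
  sec3 <- striated_section(spacing_um = 3, contrast = 0.8, noise_sd = 0.02)
  len3 <- sarcomere_length(sec3, 0.1)
  expect_false(attr(len3, "in_physiological_range"))
})

test_that("parameter recovery across a (spacing, contrast) grid", {
  spacings <- c(1.8, 2.0, 2.4)
  contrasts <- c(0.2, 0.5, 0.8)
  for (sp in spacings) {
    idx <- numeric(0)
    for (ct in contrasts) {
      sec <- striated_section(spacing_um = sp, contrast = ct,
                              noise_sd = 0.05, seed = 11)
      len <- as.numeric(sarcomere_length(sec, 0.1))
      expect_lt(abs(len - sp) / sp, 0.05)
      idx <- c(idx, sarcomere_index(radial_power_spectrum(sec, 0.1))$sarcomere_index)
    }
    ## index rank-order matches contrast rank-order
    expect_equal(order(idx), 1:3)
  }
})
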