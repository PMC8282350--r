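test_that("generators are deterministic for identical (spec, seed)", {
  s <- structure_image_spec(field_size_um = c(60, 60), pixel_size_um = 0.2,
                            n_myotubes = 2, n_nuclei = 10,
                            myotube_width_um = 12)
  a <- make_structure_image(s, seed = 5)
  b <- make_structure_image(s, seed = 5)
  expect_identical(a$fov$channels, b$fov$channels)
  expect_identical(a$truth$params, b$truth$params)
  c <- make_structure_image(s, seed = 6)
  expect_false(identical(a$fov$channels$dapi, c$fov$channels$dapi))

  n1 <- make_nmj_image(0.5, n_clusters = 6, seed = 3)
  n2 <- make_nmj_image(0.5, n_clusters = 6, seed = 3)
  expect_identical(n1$fov$channels, n2$fov$channels)

  e1 <- make_ephys_trace(ephys_trace_spec(duration_s = 5), seed = 4)
  e2 <- make_ephys_trace(ephys_trace_spec(duration_s = 5), seed = 4)
  expect_identical(e1$trace$voltage_mv, e2$trace$voltage_mv)

  m1 <- make_count_matrix(count_matrix_spec(n_genes = 50), seed = 9)
  m2 <- make_count_matrix(count_matrix_spec(n_genes = 50), seed = 9)
  expect_identical(m1$cm$counts, m2$cm$counts)
})

test_that("truth sidecars round-trip losslessly through JSON", {
  g <- make_nmj_image(0.6, n_clusters = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, path)
  back <- read_truth(path)
  expect_equal(back$kind, g$truth$kind)
  expect_equal(back$seed, g$truth$seed)
  expect_equal(back$params$coloc, g$truth$params$coloc)
  expect_equal(back$params$centers_row_px, g$truth$params$centers_row_px,
               tolerance = 1e-12)
})

test_that("structure generator renders the specified geometry", {
  ## zero contrast: stripes are uniform along the fiber axis
  s0 <- structure_image_spec(field_size_um = c(40, 40), pixel_size_um = 0.2,
                             n_myotubes = 1, myotube_width_um = 16,
                             striation_contrast = 0, n_nuclei = 0,
                             noise_sd = 0)
  g0 <- make_structure_image(s0, seed = 1)
  act <- g0$fov$channels$actinin
  stripe_rows <- g0$truth$params$stripe_rows
  stripe <- act[stripe_rows[1, 1]:stripe_rows[1, 2], ]
  expect_lt(diff(range(stripe)), 1e-12)

  ## rendered stripe width matches the spec within one pixel
  occupied <- which(rowSums(act > 0) > 0)
  expect_lt(abs(length(occupied) - 16 / 0.2), 1.5)

  ## all nuclei inside myotubes when the fraction is 1
  s1 <- structure_image_spec(field_size_um = c(80, 80), pixel_size_um = 0.2,
                             n_myotubes = 2, myotube_width_um = 25,
                             fraction_nuclei_in_myotubes = 1, n_nuclei = 12,
                             noise_sd = 0)
  g1 <- make_structure_image(s1, seed = 2)
  rows <- g1$truth$params$nuclei_row_px
  sr <- g1$truth$params$stripe_rows
  inside <- vapply(rows, function(r)
    any(r >= sr[, 1] & r <= sr[, 2]), logical(1))
  expect_true(all(inside))

  ## sub-Nyquist spacing is refused
  expect_error(structure_image_spec(pixel_size_um = 0.2,
                                    sarcomere_spacing_um = 0.3),
               "Nyquist")
})

test_that("rendered striation has its fundamental at 1/spacing", {
  sec <- striated_section(spacing_um = 2, contrast = 0.8, noise_sd = 0,
                          pixel_size_um = 0.1)
  p <- radial_power_spectrum(sec, 0.1)
  f_peak <- p$frequency_per_um[which.max(p$power)]
  df <- median(diff(p$frequency_per_um))
  expect_lt(abs(f_peak - 0.5), df + 1e-9)
})

test_that("nmj generator programs the co-localized cluster count exactly", {
  for (frac in c(0, 0.6, 1)) {
    g <- make_nmj_image(frac, n_clusters = 10, seed = 7)
    expect_equal(g$truth$params$n_coloc, round(frac * 10))
    expect_equal(sum(g$truth$params$coloc), round(frac * 10))
  }
  ## rendered masks agree with the programmed overlap
  g <- make_nmj_image(0.6, n_clusters = 10, seed = 8)
  syn <- g$fov$channels$synapsin > 0.4
  btx <- g$fov$channels$btx > 0.4
  lab <- EBImage::bwlabel(EBImage::Image(1 * btx))
  lab <- EBImage::imageData(lab)
  n_overlap <- sum(vapply(seq_len(max(lab)), function(id)
    any(syn[lab == id]), logical(1)))
  expect_equal(n_overlap, 6)
  ## geometric infeasibility is refused
  expect_error(make_nmj_image(0.5, n_clusters = 100, cluster_area_um2 = 100,
                              field_size_um = c(50, 50)),
               "invalid spec")
})

test_that("mtf generator renders projected lengths per the projection law", {
  ## flat film: full length in every frame
  wave0 <- stress_waveform(basal_kpa = 0, twitch_peak_kpa = 0,
                           tetanus_plateau_kpa = 0,
                           schedule = data.frame(
                             mode = c("rest", "twitch", "tetanus"),
                             duration_s = c(0.1, 1, 0.2)))
  v0 <- small_mtf_video(wave = wave0)
  expect_true(all(abs(v0$truth$params$projected_length_mm - 3.4) < 1e-12))

  ## constant positive stress: constant projected length below film length
  waveC <- stress_waveform(basal_kpa = 5, twitch_peak_kpa = 5,
                           tetanus_plateau_kpa = 5,
                           schedule = data.frame(
                             mode = c("rest", "twitch", "tetanus"),
                             duration_s = c(0.1, 1, 0.2)))
  vC <- small_mtf_video(wave = waveC)
  lens <- vC$truth$params$projected_length_mm
  expect_lt(max(lens), 3.4)
  expect_lt(diff(range(lens)), 1e-12)

  ## projected length never exceeds the film length
  v <- small_mtf_video()
  expect_true(all(v$truth$params$projected_length_mm <= 3.4 + 1e-12))

  ## a stress implying a bend angle beyond pi is refused
  expect_error(
    make_mtf_video(mtf_video_spec(n_films = 1), mtf_geometry(), seed = 1),
    "unsupported curl")
})

test_that("ephys generator: trivial traces and Poisson event counts", {
  sp <- ephys_trace_spec(duration_s = 5, event_rate_hz = 0, noise_sd_mv = 0)
  g <- make_ephys_trace(sp, seed = 1)
  expect_true(all(g$trace$voltage_mv == -55))

  ## single event, no noise: peak deflection equals the amplitude parameter
  sp1 <- ephys_trace_spec(duration_s = 2, event_rate_hz = 0.5,
                          amplitude_mv = 1.5, noise_sd_mv = 0)
  for (seed in 1:20) {
    g1 <- make_ephys_trace(sp1, seed = seed)
    if (length(g1$truth$params$event_times_s) == 1) {
      expect_equal(max(g1$trace$voltage_mv) - (-55), 1.5, tolerance = 1e-3)
      break
    }
  }

  ## Poisson count property at rate 0.5 Hz over 300 s
  g2 <- make_ephys_trace(ephys_trace_spec(duration_s = 300), seed = 42)
  n_ev <- length(g2$truth$params$event_times_s)
  expect_lt(abs(n_ev - 150), 3 * sqrt(150))

  expect_error(ephys_trace_spec(tau_rise_ms = 5, tau_decay_ms = 4),
               "tau_decay")
})

test_that("count generator: null matrices, Poisson limit, spiked LFC", {
  g0 <- make_count_matrix(count_matrix_spec(n_genes = 100, frac_de = 0),
                          seed = 1)
  expect_true(all(!g0$truth$params$is_de))
  expect_true(all(g0$truth$params$true_lfc == 0))

  ## small dispersion approaches Poisson on high-mean genes
  gP <- make_count_matrix(count_matrix_spec(
    n_genes = 400, n_per_group = c(25, 25), dispersion = 1e-4,
    base_mean_log_range = c(8, 10), frac_de = 0), seed = 2)
  vmr <- apply(gP$cm$counts, 1, var) / rowMeans(gP$cm$counts)
  expect_lt(abs(median(vmr) - 1), 0.15)

  ## DE genes at high mean: empirical group-mean ratio tracks 2^LFC
  ## (a gene with true LFC = 2 shows a ratio of ~4 within sampling error)
  gS <- make_count_matrix(count_matrix_spec(
    n_genes = 200, n_per_group = c(100, 100), dispersion = 0.05,
    base_mean_log_range = c(8, 10), frac_de = 0.5, lfc_sd = 1.2), seed = 3)
  de <- gS$truth$params$is_de
  ratio <- rowMeans(gS$cm$counts[de, 101:200]) /
    rowMeans(gS$cm$counts[de, 1:100])
  rel_err <- abs(ratio / 2^gS$truth$params$true_lfc[de] - 1)
  expect_lt(median(rel_err), 0.05)
  expect_lt(max(rel_err), 0.25)

  ## DE truth labels recorded, all beyond the fold-change exclusion window
  gD <- make_count_matrix(count_matrix_spec(n_genes = 500, frac_de = 0.2),
                          seed = 4)
  lfc <- gD$truth$params$true_lfc[gD$truth$params$is_de]
  expect_length(lfc, 100)
  expect_true(all(abs(lfc) >= log2(1.5)))
})

test_that("data files round-trip: fov TIFF, trace CSV, counts TSV, video", {
  g <- make_nmj_image(0.5, n_clusters = 4, seed = 1,
                      field_size_um = c(40, 40))
  tif <- withr::local_tempfile(fileext = ".tif")
  write_fov(g$fov, tif)
  back <- read_fov(tif)
  expect_equal(names(back$channels), c("synapsin", "btx"))
  expect_equal(back$pixel_size_um, g$fov$pixel_size_um)
  expect_equal(back$channels$btx, g$fov$channels$btx, tolerance = 1e-6)

  e <- make_ephys_trace(ephys_trace_spec(duration_s = 1), seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trace(e$trace, csv)
  tb <- read_trace(csv)
  expect_equal(tb$sample_rate_hz, 10000, tolerance = 1e-6)
  expect_equal(tb$voltage_mv, e$trace$voltage_mv, tolerance = 1e-9)

  m <- make_count_matrix(count_matrix_spec(n_genes = 20), seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m$cm, tsv)
  cb <- read_count_matrix(tsv)
  expect_equal(unname(cb$counts), unname(m$cm$counts))
  expect_equal(as.character(cb$groups), as.character(m$cm$groups))

  wave <- stress_waveform(schedule = data.frame(
    mode = c("rest", "twitch", "tetanus"), duration_s = c(0.1, 0.5, 0.2)))
  v <- small_mtf_video(wave = wave)
  vt <- withr::local_tempfile(fileext = ".tif")
  write_mtf_video(v, vt)
  vb <- read_mtf_video(vt)
  expect_equal(dim(vb$frames), dim(v$frames))
  expect_equal(vb$meta$fps, 100)
  expect_equal(vb$frames[, , 1], v$frames[, , 1], tolerance = 1e-6)
})
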