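## Shared small fixtures for the test suite. Everything is generated in
## code; sizes are kept small so single tests run in seconds.

## A single 50 um-wide striated myotube section, 100 x 100 um at 0.1 um/px.
striated_section <- function(spacing_um = 2, contrast = 0.8, noise_sd = 0.05,
                             seed = 1, pixel_size_um = 0.1) {
  spec <- structure_image_spec(
    field_size_um = c(100, 100), pixel_size_um = pixel_size_um,
    n_myotubes = 1, myotube_width_um = 50,
    sarcomere_spacing_um = spacing_um, striation_contrast = contrast,
    n_nuclei = 0, noise_sd = noise_sd)
  g <- make_structure_image(spec, seed = seed)
  crop_myotube_sections(g$fov, n = 1)[[1]]
}

## Small MTF scenario: geometry chosen so the default 10/25/100 kPa
## waveform stays within bend angles (0, pi).
small_mtf_geometry <- function() mtf_geometry(gel_thickness_um = 250)

small_mtf_video <- function(seed = 2, n_films = 1, pixel_size_mm = 0.04,
                            wave = stress_waveform()) {
  make_mtf_video(
    mtf_video_spec(n_films = n_films, pixel_size_mm = pixel_size_mm,
                   stress_waveform = wave),
    small_mtf_geometry(), seed = seed)
}
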