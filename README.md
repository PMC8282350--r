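# ntmetrics

Quantitative analysis of engineered neuromuscular tissues in R.

Engineered skeletal muscle tissues co-cultured with stem-cell-derived motor
neurons are a workhorse model for neuromuscular disease, but judging whether
such a tissue is "mature" requires quantification across very different
modalities: fluorescence micrographs of sarcomere structure, videos of
contracting muscular thin films (MTFs), confocal images of neuromuscular
junction (NMJ) markers, intracellular voltage recordings of spontaneous
synaptic activity, and bulk RNA-seq. ntmetrics implements that whole
measurement suite as tested, reusable R functions, for tissue engineers and
neuromuscular biologists who want the published quantification procedures
without the one-off ImageJ/MATLAB/proprietary-macro toolchain.

Every stage is paired with a synthetic-data generator that emits
machine-readable ground truth, so the entire pipeline is verifiable by
parameter recovery — no external data needed.

## What it computes

| Stage | Functions | Output |
|---|---|---|
| Muscle structure | `tissue_structure_metrics()` | nuclei/mm², myogenic index, myotube width, sarcomere index, sarcomere length |
| MTF contractility | `analyze_mtf()` | per-film stress traces (kPa), basal/twitch/tetanus, tetanus:twitch ratio |
| NMJ structure | `nmj_metrics()` | synapsin/bungarotoxin area %, cluster sizes, % co-localized clusters |
| Electrophysiology | `detect_mepsps()`, `summarize_ephys()` | mEPSP frequency, amplitude, τ_rise, τ_decay, resting potential |
| Transcriptomics | `fpkm_uq()`, `differential_expression()`, `pca_with_loadings()` | FPKM-UQ matrix, DEG table (p < 0.05, |FC| > 1.5), PCA with gene loadings |
| Statistics | `compare_groups()` | Shapiro-gated ANOVA+Tukey / Welch t / Mann–Whitney dispatch |

The scientific core, briefly: the **sarcomere index** decomposes a radially
collapsed 2D FFT power spectrum *P(f)* of a myotube crop into
*a·e^(−bf)* + Σ Gaussians and reports the area under the periodic part —
striation periodicity in [0, 1]. **MTF stress** inverts the top-view
projection of a constant-curvature film, *x = L·sin(θ)/θ* (θ = L/R), and
applies a Stoney-type plate relation
*σ = E·t_gel² / (6(1−ν)·t_tissue·R)*. **mEPSPs** are detected by threshold
crossing plus least-squares fitting of the difference-of-exponentials
template *A(e^(−t/τ_d) − e^(−t/τ_r))*. **FPKM-UQ** normalizes counts by
gene length and the sample's upper-quartile nonzero count. Details, defaults
and design rationale are in the vignette
(`vignettes/quantifying-neuromuscular-tissues.Rmd`).

## Worked example

```r
library(ntmetrics)

## Structure: render a field with known truth, then measure it
spec <- structure_image_spec(field_size_um = c(400, 400), pixel_size_um = 0.2,
                             n_myotubes = 5, n_nuclei = 120,
                             fraction_nuclei_in_myotubes = 0.7)
g <- make_structure_image(spec, seed = 1)
tissue_structure_metrics(g$fov, seed = 2)
#> <tissue_structure_metrics> 750 nuclei/mm^2 | myogenic 0.70 | width 19.9 um |
#>   sarc index 1.00 | sarc length 2.00 um (in range)

## MTF: 10 kPa basal, 25 kPa twitch, 100 kPa tetanus waveform, round-tripped
geom <- mtf_geometry(gel_thickness_um = 250)
v <- make_mtf_video(mtf_video_spec(n_films = 1, pixel_size_mm = 0.04), geom, seed = 2)
analyze_mtf(v)$summaries[[1]]
#> <contraction_summary> basal 10.00 | twitch 24.84 | tetanus 100.00 kPa | ratio 4.03

## NMJ: programmed 60% co-localization, recovered exactly
nmj <- make_nmj_image(coloc_fraction = 0.6, n_clusters = 10, seed = 3)
nmj_metrics(nmj$fov)
#> <nmj_metrics> synapsin 15.0% | btx 2.0% | 10 clusters (mean 20.0 um^2) | coloc 60%

## Ephys: detect mEPSPs in a 2-minute synthetic recording
e <- make_ephys_trace(ephys_trace_spec(duration_s = 120), seed = 7)
pre <- preprocess_trace(e$trace)
summarize_ephys(detect_mepsps(pre), pre)
#> <ephys_summary> 0.625 Hz | 0.998 mV | tau_r 2 ms | tau_d 10 ms | rmp -54.8 mV (n=75)

## Transcriptomics: normalize, test, decompose
cm <- make_count_matrix(count_matrix_spec(n_genes = 2000, frac_de = 0.1), seed = 5)
nm <- fpkm_uq(cm$cm)
sum(differential_expression(nm)$is_deg)
#> [1] 191
cumulative_pc_variance(key_gene_loadings(), 3)  # published top-3 PC variance
#> [1] 69.1
```

The numbers mean: the measured field has 750 nuclei/mm² with 70% of nuclei
inside myotubes (the programmed fraction), ~20 µm-wide myotubes and clean
2.0 µm sarcomeres (healthy range 1.8–2.4 µm); the film recovers its
prescribed stress waveform within 2% with a physiological tetanus:twitch
ratio (in-situ range 4–10); 6 of 10 receptor clusters sit on presynaptic
signal; the myotube shows 0.625 Hz spontaneous events of ~1 mV with 2/10 ms
kinetics at −55 mV rest; and 191 of 2000 genes pass p < 0.05 with |FC| > 1.5
(the matrix was simulated with 10% true DEGs, some below the cut-off).

A thin CLI over the same functions lives in `inst/scripts/ntm.R`
(subcommands `simulate`, `structure`, `nmj`, `mtf`, `ephys`, `rnaseq`,
`run`), and `run_pipeline()` orchestrates full simulate-then-analyze runs
with byte-identical reruns under a fixed seed.

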