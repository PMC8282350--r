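---
title: "Quantifying engineered neuromuscular tissues: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying engineered neuromuscular tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntmetrics)
```

ntmetrics quantifies engineered skeletal muscle tissues and the
neuromuscular junctions (NMJs) they form with co-cultured motor neurons,
across five measurement modalities: fluorescence structure metrics, muscular
thin film (MTF) contractility, NMJ co-localization, mEPSP electrophysiology,
and bulk transcriptomics. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generators emulate (and deliberately do not), and the numerical choices made
where the underlying experimental conventions were open.

## Why synthetic ground truth

The headline numbers of a wet-lab study of this kind come from specimens and
instrument-specific macros and cannot be regenerated from code alone. What a
software pipeline *can* guarantee is parameter recovery: every analysis
stage here is paired with a generator that renders data from known
parameters and emits a machine-readable truth sidecar, and the test suite
asserts that the analysis recovers those parameters within stated
tolerances. Passing these tests demonstrates that the estimators are
correct, unbiased at the simulated noise levels, and deterministic; it does
not demonstrate robustness to everything real microscopy produces (uneven
illumination, debris, focal drift, overlapping cells), which the generators
deliberately do not model — see *Limitations*.

## Muscle structure metrics

A calibrated field of view (`fov`) holds one intensity matrix per channel
role (`actinin`, `dapi`, `synapsin`, `btx`) plus the pixel size in
micrometers. Five metrics are computed:

* **Nuclei density** (`count_nuclei`): Otsu threshold on DAPI, connected
  components, area filter (default 20–500 µm², configurable because the
  original CellProfiler bounds were not published), count divided by field
  area. Thresholds are computed over the observed intensity range, so the
  counts are invariant under uniform intensity rescaling.
* **Myogenic index** (`myogenic_index`): fraction of nucleus centroids
  inside the α-actinin mask (Otsu + morphological closing with a 3 µm disc
  that bridges striation troughs). Centroid containment was chosen as the
  unambiguous rule for partially overlapping nuclei. Zero nuclei give an
  explicitly undefined result, never 0.
* **Myotube width** (`myotube_width`): random square sub-fields (default
  five of 0.1 mm²), per-object width estimated as twice the median distance
  transform along the distance-ridge (medial axis). This replaces the
  manual width measurements of the original assay with a rotation-invariant
  automated estimator; recovery on rendered stripes is within ±0.5 px.
* **Sarcomere index** (`radial_power_spectrum` + `sarcomere_index`): the
  mean-subtracted 2D FFT power of a ~50 µm-wide myotube crop is collapsed
  radially — the *mean* of `|F|²` per annulus of one frequency step — into a
  1D profile normalized to unit trapezoidal integral, DC excluded. The
  profile is decomposed by Levenberg–Marquardt least squares into an
  aperiodic exponential `a·exp(−b·f)` plus a periodic sum of Gaussians
  (default two: fundamental plus first harmonic, harmonic center constrained
  to 2× the fundamental ±10%). The sarcomere index is the integral of the
  periodic part, clipped to [0, 1].
* **Sarcomere length** (`sarcomere_length`): fiber orientation from
  intensity moments, column-wise mean profile along the fiber axis, peak
  detection (prominence ≥ 0.1× the profile range, separation ≥ 1.5 µm),
  3-point parabolic sub-pixel refinement, median inter-peak spacing.
  Lengths outside the healthy vertebrate range 1.8–2.4 µm are flagged.

Numerical choices worth knowing:

* *Radial mean, not sum.* Collapsing by annulus sums makes even a flat
  white-noise spectrum rise linearly with frequency (annulus pixel counts
  grow with radius), which the exponential term cannot follow and the
  Gaussians would absorb. The radial mean keeps a noise floor flat, so an
  unstriated myotube scores an index near 0 (< 0.05 in tests).
* *Gaussian width cap (0.15 cycles/µm) and center floor (0.2 cycles/µm).*
  Striation peaks are spectrally narrow and physiological striation periods
  are below ~5 µm. Without these bounds the periodic component can chase
  broad aperiodic structure or the sparsely-populated lowest-frequency
  annuli, making the decomposition unidentifiable on noise-dominated
  profiles. Both are arguments of `sarcomere_index`.
* *Fit fallback.* If the joint fit does not converge, the aperiodic-only
  model is kept, the index is 0 and `converged = FALSE` — degraded inputs
  degrade loudly, not silently.
* *Peak-noise floor.* `sarcomere_length` additionally requires peak
  prominence to exceed 6× the profile's pixel-scale noise (residual from a
  5-sample running median); otherwise a flat noisy profile would yield
  "peaks" at random spacings instead of the intended undefined result.

The structure generator renders stripes with a raised-cosine striation
`I(x) = base·(1 + c·cos(2πx/p))` — a single-parameter contrast model whose
fundamental frequency is exactly `1/p` — plus axis-aligned Gaussian nuclei
blobs and clipped additive Gaussian noise. Nuclei are rejection-sampled with
a minimum separation (default 8 µm) so that counting tests are not
confounded by merged components.

## MTF contractility

A muscular thin film is a muscle tissue on a flexible cantilever; tissue
contraction curls the film, and curvature reports stress. The chain is:

1. **Tracking** (`track_projected_length`): per frame and film ROI, Otsu
   threshold, largest connected component, then a sub-pixel projected length
   obtained by summing per-column occupancy fractions
   `(light − I)/(light − dark)` across the film's rows. The anti-aliased
   tip rendered by the generator makes this exact on noiseless frames;
   the series is median-filtered (3 frames) to suppress single-frame
   segmentation noise while preserving peak amplitudes. Background level is
   estimated from the whole frame because a curled film can fill its ROI.
   Sub-pixel localization matters: with a 3.4 mm film imaged at realistic
   frame sizes, pure pixel quantization of the tip position propagates to
   >10% stress error in the shallow-bend regime (sensitivity
   `dσ/σ ≈ 3·(dx/L)/θ²` for small bend angle θ).
2. **Curvature** (`curvature_from_projection`): a constant-curvature arc of
   length `L` and radius `R` projects to `x = L·sin(θ)/θ` with `θ = L/R`
   while `θ ≤ π/2`, and to `x = R` once curled past vertical
   (`π/2 < θ ≤ π`). Inversion is piecewise: bisection on `sin(θ)/θ = x/L`
   (tolerance 1e−9) for `x/L > 2/π`, identity `R = x` below. `x = L` maps
   to the flat-film sentinel (`Inf`). Constant curvature along the film
   (uniform stress) is the standard MTF assumption and matches the
   generator.
3. **Stress** (`stoney_stress`): the plate-Stoney relation
   `σ = k·E_gel·t_gel²/(6·(1−ν)·t_tissue·R)` in kPa. Substrate defaults are
   the measured hydrogel values (thickness 91.3 µm, modulus 108.3 kPa,
   ν = 0.5). The effective tissue thickness (default 15 µm) is not
   measurable in the assay and must be reviewed per experiment; `k`
   (`stoney_correction`, default 1) is a hook for modified-Stoney variants
   whose exact correction is instrument-specific. Because both parameters
   are configurable, absolute stress magnitudes are comparable only within
   a fixed geometry.
4. **Summaries** (`summarize_contractions`): basal = minimum stress during
   2 Hz pacing; twitch = mean of per-cycle maxima over the paced cycles
   (cycles delimited by the known stimulus grid — deterministic, no peak
   finding); tetanus = mean over a 1 s window at the end of the 20 Hz span;
   ratio = tetanus/twitch. Ordering violations and ratios outside the
   in-situ range [4, 10] are flagged, never corrected.

The video generator inverts this chain exactly: stress → radius → bend
angle → projected length → anti-aliased dark rectangle. It refuses bend
angles beyond π, where the curled film would overlap its base and the
projection law stops being measurable. *Demo geometry:* at the measured
substrate defaults, a 100 kPa tetanus implies θ ≈ 17 rad — far beyond that
cap — so round-trip demonstrations with the full 10/25/100 kPa waveform use
a thicker substrate (`gel_thickness_um = 250`), chosen from the closed form
`θ(σ) = 6(1−ν)·t_tissue·σ·L/(E·t_gel²)` so the entire waveform stays inside
(0, π). The default twitch pulse (150 ms raised cosine at 2 Hz) places two
near-peak samples per cycle at 100 fps, so the 3-frame median filter costs
under 1.2% of the twitch peak; all round-trip recoveries are within 2%.

## NMJ co-localization

Presynaptic (synapsin-1) and postsynaptic (α-bungarotoxin) channels are
Otsu-thresholded. The synapsin mask drops objects < 5 µm² and fills holes
(enclosed unstained interiors of axon bundles count as presynaptic
footprint). Bungarotoxin clusters below 4 µm² (configurable; the original
macro's filter is unpublished) are discarded. A cluster is co-localized
when ≥ 1 pixel overlaps the synapsin mask after dilating it by 1 px — a
registration tolerance for sub-pixel channel misalignment; a fractional
overlap criterion (`overlap_frac`) is available as an alternative. With
zero clusters the percentage is undefined, never 0. Averaging two fields
of view per coverslip is an aggregation option in the pipeline, not
hard-coded. The generator places disjoint disk clusters either fully inside
the synapsin region or clear of it by a margin exceeding the dilation, so
programmed fractions recover exactly on noiseless fields.

## mEPSP electrophysiology

Traces are low-pass filtered at 1 kHz with a zero-phase 4th-order
Butterworth (forward–backward), mirroring acquisition filtering without
phase distortion. The resting membrane potential is the mode of the voltage
histogram in 0.5 mV bins — robust to event contamination, unlike the mean.
Detection proceeds in three gates:

1. **Threshold**: upward crossings of `k·σ` (default k = 3) above a 50 ms
   running-median baseline, with σ = 1.4826 × MAD of the residual.
2. **Sustained rise**: the mean deflection over the 2 ms after the crossing
   must exceed the 2 ms before it by half a threshold. This cheap gate
   rejects sub-millisecond noise excursions (which at 1 kHz bandwidth are
   frequent at 3σ) and re-triggers on event decays, before any expensive
   fitting.
3. **Template fit**: each candidate is fit over [−5, +100] ms with
   `b + A·(exp(−t/τ_d) − exp(−t/τ_r))`, unit-peak normalized so `A` *is*
   the peak amplitude. Acceptance requires fit R² ≥ 0.5 over the window,
   `A` between the detection threshold and 15 mV, ordered time constants,
   and a peak that stays below −20 mV. The long window makes the R² gate
   selective: a noise blip explains a negligible fraction of a 105 ms
   window's variance, while a true 1 mV event at σ = 0.1 mV explains ~80%.
   Action potentials (large fast spikes, overshooting peaks) fail the
   amplitude and overshoot gates — the automated counterpart of excluding
   them by waveform shape during manual curation. The R² cut-off and both
   AP thresholds are configurable, documented surrogates for manual event
   curation.

Summaries (frequency, mean amplitude, mean τ) require at least six events
per myotube, matching the assay's reporting rule; fewer events yield an
explicitly undefined summary with a reason. RMP outside [−80, −30] mV is
flagged. Under the study conditions (0.5 Hz, 1 mV events, τ 2/10 ms,
0.1 mV noise, 300 s) detection achieves recall and precision above 0.9 with
amplitude and τ recovery within 10%, and 50 null 60 s traces produce zero
events.

## Bulk transcriptomics

* **FPKM-UQ** (`fpkm_uq`): `counts·10⁹ / (gene_length_bp · UQ_s)` with
  `UQ_s` the 75th percentile (linear interpolation) of the sample's nonzero
  gene counts; genes with zero counts everywhere are dropped first. The
  nonzero-gene quartile is the annotation-free surrogate for the
  protein-coding-gene quartile used by reference pipelines; it preserves
  exact per-sample scale invariance.
* **Differential expression** (`differential_expression`): Welch t on
  `log2(fpkm_uq + 1)` — the undisclosed "gene-specific analysis" of the
  commercial pipeline is approximated by the field's default two-group
  test; a pooled-variance option exists. Linear fold change is computed on
  the linear scale with a 10⁻³ pseudo-mean for stability at low expression.
  A gene is a DEG when p < 0.05 and linear |FC| > 1.5 in either direction;
  no multiple-testing correction by default, mirroring the plain p = 0.05
  convention (a BH option exists). With n = 3 per group Welch is mildly
  conservative on NB counts: the null type-I error averages ≈ 0.032 across
  replicate simulations, within the accepted 0.03–0.08 band.
* **PCA** (`pca_with_loadings`): samples over genes on gene-centered
  `log2(fpkm_uq + 1)`. Loadings are reported as gene–score Pearson
  correlations, which are bounded by 1 and consistent with published
  loading magnitudes (e.g. 0.99); whether the original tables used
  eigenvector weights or correlations is not stated, so the correlation
  convention is documented here. A top-2% filter (`top_loading_genes`)
  mirrors the published key-gene selection. The packaged table of published
  per-component variances (35.55, 24.51, 9.04%) sums to 69.1% over the
  first three components — the "roughly 69%" bookkeeping check.
* **Heatmap ordering** (`cluster_heatmap_order`): average-linkage
  clustering on `1 − r` over gene-standardized values; constant genes are
  dropped with a warning.

The count generator draws negative-binomial counts with log2-uniform
baseline means (default range 2¹–2¹⁰, spanning lowly to highly expressed
genes), dispersion 0.1 (typical bulk RNA-seq), and true log fold changes
resampled outside the |LFC| < log2(1.5) window so every programmed DEG
exceeds the pipeline's fold-change cut-off in truth.

## Group statistics and orchestration

`compare_groups` reproduces the study's dispatch: two-factor designs use
two-way ANOVA (type-II sums of squares — the documented choice for
unbalanced cell-source × timepoint designs) with Tukey comparisons;
one-factor and two-group designs gate on per-group Shapiro–Wilk normality,
using ANOVA + Tukey / Welch t when normal and Mann–Whitney otherwise;
significance at p < 0.05.

`run_pipeline` chains simulate-then-analyze stages, writes CSV/JSON tables,
a manifest with MD5 hashes, the effective configuration, and a run log with
package and R versions and the seed. The log deliberately omits wall-clock
runtime so that a rerun under the same seed is byte-identical — determinism
is part of the output contract. Demo problem sizes (400 µm structure
fields, 20–60 s traces, 2-film videos at 0.04–0.05 mm/px, 400–1500 genes)
are chosen so a full run completes in about a minute on one CPU while every
estimator still operates far from its resolution limits.

## Limitations

* The generators emulate geometry, periodicity, counts and noise — not
  optics. No point-spread function, uneven illumination, autofluorescence,
  out-of-focus light or stitching artifacts; myotubes are straight and
  parallel; nuclei do not touch. Real-data performance of the thresholding
  steps will be worse and should be validated per dataset.
* Absolute MTF stresses depend on the effective tissue thickness and the
  exact Stoney correction, both configuration values; only within a fixed
  geometry are magnitudes comparable.
* The mEPSP detector assumes a stationary baseline after median correction
  and non-overlapping events at the simulated rates; bursts of overlapping
  events will merge.
* The DE test is a per-gene two-sample t-test; it does not borrow strength
  across genes the way shrinkage estimators do, and with n = 3 it is
  conservative.
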