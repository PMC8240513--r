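---
title: "Multi-sensor ground cover and its reliability across a diurnal schedule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor ground cover and its reliability across a diurnal schedule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groundcover)
```

## The problem

Canopy ground cover (GC) — the fraction of soil surface covered by foliage —
is a standard measure of crop establishment and early vigour, and a
selection target in wheat breeding. Ground-based phenotyping platforms
estimate it concurrently from three sensing modes with very different
physics:

* **RGB imagery** (passive): a pixel is vegetation when the greenness index
  $VI = (G - R)/(G + R)$ exceeds 0; plot GC is the mean green-pixel fraction
  over the plot's images.
* **LiDAR red reflectance** (active): green tissue absorbs the red laser, so
  returns with intensity below 5 (0–255 scale) are vegetation.
* **LiDAR height** (active): returns more than 10 cm above local ground are
  vegetation.
* **Active NDVI** (active): the sensor integrates reflectance over its
  footprint and reports NDVI in [0, 0.99] directly; plot NDVI is the mean of
  the readings assigned to the plot.

For breeding the question is not absolute accuracy but *reliability*: can a
method discriminate genotypes consistently across times of day, light
levels and leaf moisture? This package implements the estimators, the
reliability statistics, and a synthetic field-trial simulator so the whole
analysis is testable end to end without field data.

## The simulator: what it emulates

`simulate_trial()` generates a partial-replicate trial: by default 192
plots and 99 genotypes (each genotype on one or two plots; mean replication
192/99 ≈ 1.94), laid out on an 8 × 24 field grid. Plots are 6 m long with
seven sown rows at 0.25 m spacing and 0.4 m paths — the geometry the plot
segmentation relies on.

True ground cover is logit-normal:
$$GC = \mathrm{logit}^{-1}(\mu + g + r + c + \epsilon),$$
with independent Gaussian genotype, field-row, field-column and residual
plot effects. The link scale keeps GC strictly inside (0, 1) and makes the
variance components directly interpretable. Defaults
($\mu = -0.2$, $\sigma^2_g = 0.12$, $\sigma^2_{row} = \sigma^2_{col} = 0.02$,
$\sigma^2_\epsilon = 0.10$) give a mean GC near 0.45 — an early-season,
tillering-stage canopy — and a plot-level repeatability
$\rho = \sigma^2_g/(\sigma^2_g + \sigma^2_\epsilon/n_{rep}) \approx 0.7$,
the level typical of well-run early-vigour trials. Canopy height rises
linearly from 5 cm toward 30 cm with true GC, so early canopies sit mostly
below the 10 cm height threshold and the height method underestimates GC —
a deliberate, realistic bias.

`make_event_schedule()` builds the diurnal sampling schedule: 13 hourly
events, 12:00–18:00 on day one and 07:00–12:00 the next morning. Each event
carries an *effective light* level (MJ·m⁻²·h⁻¹ during the traverse) and a
dew flag (07:00 and 08:00). The packaged fixture
(`met_schedule_path()`) transcribes the recorded hourly weather of the two
2017 field campaigns the schedule mirrors, including air/dewpoint
temperature and relative humidity. Note one deliberate difference: the
recorded *hourly-mean* radiation at 07:00 is 0.0 because the hour starts at
sunrise, yet a traverse beginning at 07:00 happens almost entirely in
daylight. The default schedule therefore assigns small positive effective
light (0.3, 0.6) to the two early-morning events and keeps 18:00
(0.1) as the darkest sampling — matching the observed failure mode of
passive imaging at dusk rather than the bookkeeping of hourly averages.

### Sensor models

**RGB.** Each pixel is vegetation with probability `true_gc`. Vegetation is
green-dominant (60, 120, 50), soil red-dominant (120, 90, 60); the rendered
channel is `ambient + base × exposure + noise` with
`exposure = min(1, radiation)²`, per-pixel Gaussian noise (sd 10) and a
per-image green-channel colour cast (sd 2) that does *not* scale with
exposure. The quadratic exposure curve makes the green–red contrast sink
below the noise floor as light fails: at full light the expected green
fraction is within ~0.01 of true GC; in darkness per-pixel classification
is a coin flip and the colour cast — now large relative to the vanished
signal — destroys the genotype ranking. This is the mechanism by which the
simulator encodes the known light sensitivity of passive imaging.

**LiDAR.** Returns are vegetation with probability `true_gc`. Intensity is
bimodal — dry vegetation N(2, 1.5²), soil N(30, 8²), clipped to [0, 255] —
so the fixed threshold at 5 misclassifies only ~2% of vegetation and
~0.1% of soil. Under dew the vegetation intensity shifts up by 6: water on
the leaves degrades the reflectance separation and most canopy returns
cross the threshold, so red-reflectance GC collapses while the height
channel is untouched. (The direction of this shift is pinned to what is
observed in the field — dew lowers reflectance-based GC; the optical
mechanism itself is unsettled.) Vegetation height is
`canopy_height × Beta(2, 2)`; soil height is folded-Gaussian roughness
(sd 2 cm).

**NDVI.** Readings are
`ndvi_soil + (ndvi_veg − ndvi_soil) × true_gc + noise` (0.15, 0.85,
sd 0.02), clipped to the instrument range [0, 0.99], spaced
`speed / rate` metres apart. The generator ignores light and dew *by
construction*: the stability of the active sensor is an assumption of the
simulator, not a finding. What the pipeline's tests then show is that the
analysis machinery correctly *detects* stability where it exists and
instability where it does not — not that any real instrument is stable.

### What the simulator does not model

No radiometric camera model, lens distortion, over-exposure saturation at
midday, wind or motion blur; no 3-D canopy with occlusion (vegetation
probability is i.i.d. per pixel/return, so there is no spatial texture); no
GPS/IMU geocoding error (positions are exact 1-D along-track metres); no
assignment loss of images between plots. Consequently passing tests
demonstrate the correctness of the estimators and statistics under the
stated generative assumptions, not field performance of any sensor.

## Estimation

`sampling_region()` excludes a 0.5 m buffer at each plot end and the two
outermost rows: a 6 m × 7-row plot leaves a 5 m × 1.25 m region (five inner
rows plus half a row spacing each side; the exact cross-track margin of
"about 1 m" regions is a documented geometry choice, not a measurable
fact). Intervals are half-open `[start, end)` so a point at the boundary
belongs to exactly one side. `assign_to_plot()` selects image and reading
positions inside the region; `clip_scan()` does the same in 2-D for LiDAR.

All thresholds are strict, following the estimators' definitions: VI
exactly 0, intensity exactly 5 and height exactly 10 cm classify as
non-vegetation, soil and ground respectively. Black pixels (R = G = 0) get
VI 0 — black is not green canopy. Ground level for the height method is
the 5th percentile of raw z in the region (robust to up to ~5% low
outliers; the testable contract is translation invariance); with fewer
than 50 returns the minimum is used instead, with a warning. Missing
sensors yield flagged `NA` rows in the GC table, never silent zeros: the
statistics must distinguish absent from bare soil.

## Reliability statistics

For each event × method, `fit_random_effects()` fits
`value = μ + genotype + row + col + ε` by REML (via lme4) and predicts
genotype BLUPs. Spatial trend is represented by row and column random
effects only — deliberately simpler than 2-D spline surfaces used with
real field data, and correctly specified for the simulator, which generates
exactly row + column structure. Repeatability is
$\rho = \sigma^2_g/(\sigma^2_g + \sigma^2_\epsilon/n_{rep})$ with
$n_{rep}$ the mean replication (`n_plots / n_genotypes`, the trial-level
convention, not a per-genotype harmonic mean). Two degenerate cases are
explicit: identical values give all-zero variances with a warning, and
$\rho$ is `NA` when both variances vanish.

`icc_matrix()` computes, per method, the Pearson correlation of per-plot
values between every pair of sampling events (intraclass correlations);
`phenotypic_corr_matrix()` correlates genotype means (μ + BLUP; using raw
BLUPs gives identical r) between methods at one event. Significance stars
follow the strict ladder `****` < 0.0001, `***` < 0.001, `**` < 0.01,
`*` < 0.05, computed from the t transform with n − 2 df;
pairwise-complete deletion, no multiple-testing correction.

## Numerical and design choices

* **Determinism.** Every generator takes a seed; `render_bundle()` derives
  one 31-bit sub-seed per (master seed, plot, event) with an integer hash,
  so single bundles are reproducible in isolation and two runs of
  `run_experiment()` with one master seed write byte-identical CSVs.
* **Problem sizes.** Default images are 40 × 56 px with ~6 per plot, scans
  2000 returns, NDVI 50 readings in-region. At these sizes counting noise
  (binomial sd ≲ 0.01) is far below the plot-level residual spread
  (sd ≈ 0.08 on the GC scale), so estimator noise does not distort the
  variance decomposition, while a full 192 × 13 experiment stays in the
  tens of seconds. The recovery tests use larger instruments (200 × 300 px,
  10⁴ returns) where concentration within ±0.05 is provable.
* **REML settings.** lme4 defaults with singular-fit checks silenced:
  boundary estimates (a variance at 0) are legitimate, common at events
  where a sensor carries no signal, and must not abort the pipeline.
* **Image trigger phase.** Uniform random per traverse over one trigger
  interval, extending half a path width past each plot end; a 6 m plot
  yields 6–7 trigger positions of which 5 fall inside the buffered region.
  Real platforms lose images between plots (field reports average ~3 per
  plot); that loss process is not modelled.
* **Dew constraint.** The schedule refuses dew flags at radiation above
  0.6 MJ·m⁻²·h⁻¹ — dew forms overnight and burns off quickly; a sunlit
  dewy canopy would be an inconsistent simulation state.

## Known limitations

The absence of spatial texture makes image pixels exchangeable, so
permutation invariance holds exactly — convenient for testing, unrealistic
for segmentation research. The row/column spatial model would be
misspecified for real fields with smooth 2-D trends. Reliability
conclusions transfer to real data only to the extent the generative
assumptions (bimodal reflectance, light-scaling contrast, stable NDVI)
hold; the package's contribution is the tested machinery, and the packaged
met fixture plus the file-based interfaces (`estimate_from_files()`,
PNG/CSV/PLY readers) are the on-ramp for real sensor exports.
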