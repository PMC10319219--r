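---
title: "Methods: synergic SAR flood mapping and cropland damage scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergic SAR flood mapping and cropland damage scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodscope)
```

## The model and its assumptions

`floodscope` maps inundation by change detection on multi-temporal SAR
backscatter. The physical premise is simple: calm open water is a specular
reflector, so a flooded pixel's backscatter collapses to roughly the
open-water level (around −20 dB at C-band VV) while it is inundated, and
recovers afterwards. A dry reference-period stack R and a flood-period
stack F therefore separate three populations:

* unchanged land — similar in R and F;
* permanent water — dark in both;
* new inundation — land-like in R, water-dark in F.

Two indices target the third population. The CDAT difference
`D = min(F) − min(R)` uses minimum compositing on both sides so that even a
single inundated acquisition in a sparse flood-period series is captured.
The NDFI, `(mean(R) − min(R∪F)) / (mean(R) + min(R∪F))`, anchors the
contrast at the pixel's *normal* state (the reference mean) rather than its
reference minimum, which makes it sensitive to transient darkening but
insensitive to surfaces that are always dark. The final product is the
consistency ("synergy") map — the pixelwise AND of the two thresholded
maps. The two algorithms have nearly independent speckle-driven false-alarm
patterns, so intersecting them suppresses false positives at a small cost
in omission.

Key assumptions: stacks are radiometrically calibrated, terrain-corrected,
co-registered and in dB (a `to_decibel()` helper is provided for linear
inputs); the scene is predominantly non-flooded so index statistics are
meaningful; and flooding produces open-water backscatter (emergent
vegetation, wind roughening and urban double bounce violate this and are
out of scope).

## The decision-tree filters

Before thresholding, three eligibility filters remove pixels whose index
values would otherwise contaminate both the threshold statistics and the
map:

1. **Terrain** — slope over the DEM via Horn's 3×3 method; pixels steeper
   than 5° (inclusive cutoff: slope ≤ 5° is eligible) are removed, since
   backscatter changes on slopes are dominated by viewing geometry.
2. **Background** — pixels with `D = 0` (|D| ≤ 10⁻⁶ dB) did not change.
   This removes unchanged land and, importantly, permanent water, which is
   dark in both periods. The rule is defined on the CDAT difference image
   only; applying it to NDFI raises an error.
3. **Seasonal change** — only pixels whose flood-period minimum falls
   strictly below −19 dB remain candidates. Seasonal darkening (harvest,
   tillage, senescence) rarely reaches open-water levels, so this is a
   land-water boundary, not a change test. It guards both algorithms.

Masks are intersected, so filter order is irrelevant; the test suite checks
this property explicitly.

## Thresholds: statistical and sample-calibrated

Two routes resolve the decision threshold T, reflecting the two ways it is
chosen in practice:

* `adaptive_threshold()`: `T = mean(I) − Kc·std(I)` with `Kc = 1.5`,
  computed over the *filter-eligible* pixels of the index raster. The
  standard deviation is the population form by default (`std_kind =
  "sample"` switches to n−1); for the large pixel counts involved the
  difference is negligible, but the choice is stated so results are exactly
  reproducible.
* `calibrate_threshold()`: exhaustive search over thresholds derived from
  labeled samples. Candidates are the midpoints between consecutive sorted
  unique training-sample index values, plus one candidate below the minimum
  and one above the maximum. Midpoints rather than the values themselves
  matter for the separable case: the optimal threshold then falls strictly
  inside the gap between the two classes instead of on a sample value. The
  sample set is re-partitioned `n_repeats = 5` times into 1/3 training and
  2/3 validation; each repeat's best candidate is scored by validation
  overall accuracy and the best repeat wins. Everything is deterministic
  given the seed.

The pipeline defaults to the calibrated route. This is a deliberate,
scene-dependent choice: the `mean − Kc·std` rule presumes that the
thresholded population is dominated by unchanged pixels, with changed
pixels in the negative tail. On the synthetic scenes the seasonal filter is
extremely effective — after it, the eligible population is almost purely
flooded — so the statistical rule places T deep inside the flooded
distribution and under-detects. That behavior is retained and observable
(`threshold = "auto"`), because it is a faithful property of the rule, and
the calibrated route is the default exactly as one would do when labeled
samples are available. Classification is strict (`index < T`); a pixel
exactly at the threshold is non-flooded.

## The synthetic scene generator

`scene_config()` / `generate_scene()` emulate a small inland floodplain
with every feature the method must confront, and nothing it cannot:

* **Speckle** — multiplicative Gamma noise with shape L (the equivalent
  number of looks) applied in the *linear power* domain and converted back
  to dB; this is the standard statistical model of L-look SAR intensity.
  `looks = Inf` disables it. An additional Gaussian spread `sigma_db`
  models class heterogeneity in dB. Defaults: land −8 dB, water −20 dB,
  σ = 1 dB, L = 10 — chosen so the −19 dB cutoff sits between the two
  class means and speckle overlap is realistic but not pathological.
* **Three nested stage floods** spreading from a permanent lake, so truth
  intensity is 3 nearest the water and 1 at the fringe; five historical
  annual extents for frequency and newly-added accounting.
* **A hill strip** with a 0.2 m/m DEM ramp (≈11°, safely above the 5°
  cutoff).
* **Seasonal-change confounders** — patches that darken to −21 dB in the
  flood period only, labeled non-flood in the truth. The value is *below*
  the −19 dB cutoff on purpose: these patches defeat the filter cascade
  and mark the method's honest failure mode, visible in every accuracy
  number the package reports.
* **Cropland** (91% rice) overlapping the flood zone, with vegetation-index
  trajectories whose post-flood depression grows with truth intensity
  (δ = 0.15 / 0.30 / 0.45 for intensities 1–3, noise sd 0.02).

The historical NDVI series carries a deterministic year-effect pattern of
amplitude 0.1 around the baseline in addition to noise. This keeps the
per-pixel historical median at the baseline and the maximum 0.1 above it,
so the mVCI denominator is well defined even in noise-free runs — a
generator design choice, not a property of real data.

What the generator does **not** emulate: orbit geometry, layover/shadow,
polarimetric effects, wind-roughened water, partial-pixel flooding, cloud
contamination of the optical bands, and real spatial autocorrelation of
land cover. Passing tests therefore demonstrate algorithmic correctness
and statistical behavior under the stated noise model — not performance on
real imagery, where reference-period selection and these unmodeled effects
dominate the error budget.

Labeled samples follow a 3000-point design (1290 flooded / 1710
non-flooded, i.e. a 0.43 flooded fraction; 1000 train / 2000 validation),
drawn without replacement after eroding each class mask by one pixel so no
sample sits on a mixed edge pixel.

## Numerical and accounting conventions

* **Nodata** is `NA` in memory; on disk −9999 (continuous) or 255
  (categorical). Statistics never include nodata; composites use whatever
  valid observations a pixel has, and only an all-nodata history yields
  nodata.
* **Zonal accounting** assigns each pixel to the first zone containing its
  center point. The rule is deterministic and makes zone totals exactly
  additive (verified to 10⁻⁹ km²); exact polygon clipping would differ at
  boundary pixels.
* **Areas** are pixel counts × pixel area; geographic (degree) grids are
  refused rather than approximated.
* **Percent shares** are rounded half away from zero to integers, the
  convention matching printed shares like 29% and 46%.
* **Geometrical-interval reclassification** builds breaks whose widths
  form a geometric progression across the data range. The common ratio r
  is selected by a dense log-spaced search over [1/8, 8] minimizing the
  variance of per-class pixel counts (ties prefer r closest to 1); the
  originating GIS implementation of this classifier is undocumented, so
  the definitional constant-ratio property of the breaks is the tested
  contract, not a particular r. Classes are oriented so the most negative
  interval (largest VI decline) is class 3, and for damage scoring,
  non-declines (≥ 0) are forced to class 0.
* **Severity degree** `(NDVI_cls + EVI_cls + DVDI_cls + intensity)/4` is
  evaluated only on flooded cropland (intensity ≥ 1), so it lies in
  (0, 3]; slight/moderate/severe are the intervals (0,1], (1,2], (2,3].
  The reclass statistics are computed over flooded-cropland pixels only,
  so unaffected land does not dilute the class breaks.
* **VI baselines**: the pre-flood NDVI mean is the average of the same
  seasonal window over the five prior years of the historical series; DVDI
  compares the post-flood window (September–October) against the pre-flood
  window (June–July) of the flood year, both anchored by the per-pixel
  historical median/maximum. Per-pixel (not regional) climatology is used,
  as is standard for VCI-family indices.
* **Speckle filtering** is a 3×3 focal median per acquisition, applied
  before compositing (configurable off, and off by default when the scene
  is simulated without speckle — median-filtering a noise-free piecewise-
  constant scene would only erode region corners). The median was chosen
  over a boxcar for edge preservation and determinism.
* **NDFI domain**: computed in dB, consistent with a negative calibrated
  threshold; `min(R∪F)` is the minimum over the concatenation of both
  stacks.

## Problem sizes

The default study conditions are a 120 × 120 grid at 10 m (1.44 km²),
five reference and three-per-stage flood acquisitions, 3000 samples, and
five seeds for seed-averaged accuracy; unit tests use 60 × 60 scenes with
600 samples. These sizes were chosen so the whole suite and the acceptance
script re-run in minutes while every statistical check (speckle-mean
convergence, seed-averaged accuracy, calibration recovery) retains
comfortable margins.

## Known limitations

* The ESRI ASCII grid interface carries no projection metadata beyond the
  units sidecar; reprojection and non-square pixels are out of scope.
* The statistical threshold route is unreliable whenever the filter
  cascade leaves a nearly pure flooded population (see above); use the
  calibrated route or a fixed threshold in that regime.
* The seasonal filter's fixed cutoff assumes calm open water; wind
  roughening or emergent vegetation raises flood backscatter above it.
* Damage scoring requires a usable historical NDVI record; pixels whose
  historical maximum equals their median are excluded.
* The confounder patches demonstrate that a backscatter drop below the
  seasonal cutoff in the flood period is indistinguishable from flooding
  by this method alone; resolving it needs ancillary data, which is
  precisely why such patches are part of the default scene.
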