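# floodscope

Flood mapping from multi-temporal SAR backscatter by synergic change
detection, with downstream flood-severity characterization and cropland
damage scoring.

## The problem

Monitoring large summer floods from space is easiest with synthetic
aperture radar (SAR): open water is a smooth, specular surface that returns
very little energy to the sensor, so inundated land drops to strongly
negative backscatter (dB) regardless of cloud cover. The difficulty is
separating *new* inundation from everything else that is dark or changing:
permanent lakes and rivers, radar speckle, hillside viewing-geometry
artifacts, and seasonal land-cover change. `floodscope` implements a
change-detection workflow that addresses each of these explicitly, and then
quantifies what the flood did: how often each pixel flooded within the
season (intensity), how often across years (frequency), how much area
flooded that never had before, and how badly the flooded cropland was
damaged.

The package is aimed at remote-sensing and agricultural-monitoring
scientists who want a tested, reproducible desk-scale implementation of
this workflow. It ships a synthetic scene generator with known ground
truth, so every stage — from speckle statistics to the damage report — is
exercised end to end without downloading satellite data.

## The method

Two change-detection indices are computed per pixel from a reference-period
stack R (dry season) and a flood-period stack F, both in dB:

- **CDAT** (change detection and thresholding):
  `D = min(F) − min(R)`; new inundation makes D strongly negative.
- **NDFI** (normalized difference flood index):
  `NDFI = (mean(R) − min(R∪F)) / (mean(R) + min(R∪F))`, where `min(R∪F)`
  is the per-pixel minimum over both stacks together; transient flooding
  drives NDFI negative on negative-dB imagery.

A decision-tree filter cascade removes non-flood pixels before
thresholding: (1) terrain — slope over 5° (Horn's method on the DEM) is
ineligible; (2) background — pixels with `D = 0` did not change (this also
removes permanent water, dark in both periods); (3) seasonal — only pixels
whose flood-period minimum falls below −19 dB (an open-water level) remain
candidates. The threshold is either statistical, `T = mean(I) − Kc·std(I)`
with `Kc = 1.5`, or calibrated by exhaustive search over labeled samples
(five repeated train/validation re-partitions, 1/3–2/3). A pixel is flooded
when its index is strictly below T and all filters admit it. The final map
is the **synergy (consistency) map**: the pixelwise AND of the CDAT and
NDFI maps, which suppresses single-algorithm speckle false alarms.

Downstream, stage maps are summed into an intensity map (1–3), annual maps
into a frequency map (0–6), and the newly flooded area is reported as a
percentage of the maximum ever-flooded union of prior years. Accuracy is
assessed with a confusion matrix (OA/UA/PA/F1) against labeled points and
cross-checked against an optical water rule
(`LSWI > EVI AND NDVI > 0.1`) aggregated to zones. Cropland damage combines
three reclassified vegetation-index changes with flood intensity:

    severity degree = (NDVI_reclass + EVI_reclass + DVDI_reclass + intensity) / 4

where DVDI is the change in the modified vegetation condition index
`mVCI = (NDVI − NDVI_med) / (NDVI_max − NDVI_med)` anchored at the
historical per-pixel median and maximum, and each component is reclassified
to 0–3 by geometrical intervals (break widths in geometric progression).
Degrees in (0,1], (1,2], (2,3] are slight, moderate and severe damage.

## Worked example

```r
library(floodscope)

cfg <- scene_config(seed = 42)     # 120 x 120 px at 10 m, 10-look speckle
result <- run_flood_pipeline(cfg)
result
#> <fs_pipeline_result>
#>   stage areas (km2): 0.604, 0.413, 0.235
#>   validation OA: 96.45%  F1: 0.960
#>   newly flooded: 0.130 km2 (27% of max ever flooded)

result$metrics
#> # A tibble: 1 × 6
#>      oa ua_flooded pa_flooded ua_nonflooded pa_nonflooded    f1
#>   <dbl>      <dbl>      <dbl>         <dbl>         <dbl> <dbl>
#> 1  96.4       92.4        100           100          93.8 0.960

result$damage$report$summary
#> # A tibble: 3 × 3
#>   class    area_km2 share_percent
#>   <chr>       <dbl>         <dbl>
#> 1 slight      0.227            37
#> 2 moderate    0.193            32
#> 3 severe      0.186            31

glance(result$thresholds$cdat)
#> # A tibble: 1 × 4
#>       T method        oa algorithm
#>   <dbl> <chr>      <dbl> <chr>    
#> 1 -6.42 calibrated  96.7 CDAT
```

The three stage areas shrink because the stage extents are nested in the
default scene; producer's accuracy of 100% with user's accuracy of 92%
means every truly flooded sample was recovered while the deliberate
seasonal-change confounder patches (dark in the flood period only, below
the −19 dB cutoff) produce the expected false alarms. `autoplot()` renders
any raster (`autoplot(result$intensity, discrete = TRUE)`), and
`tidy()`/`glance()` methods turn thresholds and confusion matrices into
tibbles.

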