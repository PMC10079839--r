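# tidalmarsh

Early indicators of the transition from bare tidal flat to vegetated salt
marsh.

Estuarine tidal flats can shift, over a decade or two, from bare mud to
vegetated marsh — a change that is hard to reverse and that reshapes flood
safety, habitat and navigation management. Before pioneer vegetation
arrives, three things happen in sequence on the upper flat: it accretes
above neap high water level (NHWL), it flattens, and metre-scale
ridge–runnel *micro-topography* (vertical relief of a few centimetres)
appears on the flattest sections. `tidalmarsh` implements the full
analysis chain that turns public monitoring data — tide-gauge records,
lidar DEMs and false-colour orthophotos — into those indicators, plus a
drainage model that explains why the patterns form only on gentle slopes,
and a synthetic-estuary generator with known ground truth so that every
stage is testable offline.

The package is aimed at coastal ecologists, ecogeomorphologists and
estuary managers working with multi-year raster monitoring archives.

## The quantities at the core

**Skipped tidal inundations** (per elevation *z*, from a tide-gauge
record):

    skipped(z) = (1 − cycles_inundated(z) / cycles_total) × 100 %

where a high tide inundates *z* only when its peak level exceeds *z*
strictly. `skipped = 0` at and below NHWL; vegetation establishment is
essentially impossible there.

**Micro-topography intensity**: the sample standard deviation of the
near-infrared (NIR) band inside 10 × 10 m frames. Fine relief modulates
drainage and surface wetness, hence NIR reflectance, so windowed NIR
variability detects relief that is below the vertical resolution of the
available lidar. The metric is calibrated against the SD of local slope
from high-resolution elevation data via log–log regression.

**Establishment probability surface**: for every pair of consecutive
campaigns, each bare 10 m cell is binned by (intensity × skipped %) on an
85 × 101 grid; the probability per bin is the proportion of at-risk cells
that became newly vegetated, pooling counts across pairs, with bins under
30 cells excluded.

**Drainage model**: thin-layer surface water on an inclined bed S with
autocorrelated noise evolves by the nonlinear diffusion

    dW/dt = ∇·( K · W · ∇(W + S) ),   K = 1

on a grid with an elevation-offset periodic wrap in the down-slope
direction. The *flow concentration* — the SD across the grid of the
time-averaged water depth — drops from pooled/channelised drainage on
near-horizontal beds to uniform sheet flow by 1.5°, explaining the
observed low-slope (< 0.3°) confinement of the patterns.

## Worked example

```r
library(tidalmarsh)

# a fully synthetic estuary: tides, accreting DEMs, orthophotos, vegetation
cfg   <- synth_config(rows = 160, cols = 160, years = 2004:2008, seed = 42)
scene <- synth_estuary(cfg)

# the early-indicator report for the upper-flat unit
rows <- 1:5; cols <- 1:16
report <- early_indicator_report(
  lapply(scene$dem10,      crop_grid, rows = rows, cols = cols),
  lapply(scene$exposure10, crop_grid, rows = rows, cols = cols),
  lapply(scene$slope10,    crop_grid, rows = rows, cols = cols))
report[, c("year", "mean_skipped_pct", "mean_slope_deg",
           "accretion_cm_yr", "flagged")]
#>   year mean_skipped_pct mean_slope_deg accretion_cm_yr flagged
#> 1 2004             49.2          0.187              NA   FALSE
#> 2 2005             50.3          0.187              NA   FALSE
#> 3 2006             51.5          0.187               2    TRUE
#> 4 2007             52.7          0.187               2    TRUE
#> 5 2008             53.7          0.187               2    TRUE
attr(report, "first_flag_year")
#> [1] 2006
```

The unit sits above NHWL (half its tidal cycles are skipped), accretes at
the configured 2 cm yr⁻¹ (recovered by the trend regression once three
years are available), and its mean 10 m slope of 0.19° is under the 0.3°
boundary below which micro-topographic patterning appears — so from 2006
onward it is flagged as approaching the transition to marsh.

The per-scene NDVI threshold and the drainage model:

```r
thr <- fit_ndvi_threshold(as.vector(as.matrix(ndvi(scene$orthos[["2008"]]))))
thr
#> <ndvi_threshold> sediment peak: 0.099, vegetation peak: 0.493, threshold: 0.296

res <- simulate_drainage(make_plane(nx = 128, inclination = 0.05,
                                    sigma_s = 2.5, seed = 1))
res
#> <drainage_result> flow concentration: 0.39236 cm, steps: 4931, converged: TRUE
#>   mass-balance residual: 1.2e-14 (relative)
```

At 0.05° the drained water concentrates strongly (flow concentration
0.39 cm — pooling in the bed-noise lows); repeating across inclinations
with `slope_sweep()` traces the decline toward sheet flow at 1.5°.

`run_pipeline()` executes the same chain from a YAML/CSV/ASCII-grid
manifest and writes every table as CSV with a provenance log;
`run_demo()` generates a rising flat and a static steep control and
verifies that only the former is flagged, before its first establishment.

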