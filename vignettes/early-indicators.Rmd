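---
title: "Early indicators of tidal-flat to marsh transitions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early indicators of tidal-flat to marsh transitions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `tidalmarsh`, in the spirit of a methods appendix. It
states how each quantity is defined and computed; every empirical number
the package claims is computed by the test suite or by
`scripts/acceptance.R`, not asserted here.

## The tidal-exposure metric

A tide-gauge record is reduced to its high-tide peaks: strict local
maxima of the level series, thinned so retained peaks are at least 10 h
apart (the default suits a semidiurnal regime; when two candidates fall
inside one window the higher wins). The percent of skipped tidal
inundations at elevation $z$ is

$$\mathrm{skipped}(z) = \left(1 -
  \frac{\mathrm{cycles}_{\mathrm{inundated}}(z)}
       {\mathrm{cycles}_{\mathrm{total}}}\right)\times 100\,\%$$

with the tie-break that a peak exactly at $z$ does **not** inundate it
(the level must reach *above* the elevation). The exposure curve is
therefore a right-continuous step function with jumps exactly at the
peak levels, and is evaluated exactly from the retained peaks rather
than from a tabulated grid; a property test checks equality with an
exhaustive recount on seeded records. Neap high water level (NHWL) is
operationalised as the lowest elevation with positive skipped percent.
Between gauges, skipped percent is interpolated linearly in the
along-estuary coordinate at fixed elevation, clamped to the nearest
station outside the covered range; the estuary axis is the map x
coordinate by default and is a configuration choice. Adding a constant
to both the levels and the elevations leaves every output unchanged
(datum covariance), which is also tested.

Both raw series maxima and agency-published high-water tables can drive
the metric: a table is simply a `water_level_series` whose samples are
the published peaks.

## Raster machinery

Grids are matrix-backed `grid_raster` objects (cell size in metres,
row 1 at the northern edge, `NA` for nodata, a semantic kind tag) with
plain-text ESRI ASCII I/O. Slope uses Horn's 3×3 finite difference —
the default of the standard GIS terrain routines — with elevations in
cm converted to metres before the arc-tangent; border cells are nodata.
Windowed statistics use **non-overlapping tiles**: the 10 × 10 m frames
of the intensity metric tile the scene, giving an output raster at
10 m, which matches the coarsening step of the reference procedure. A
centred moving-window variant exists behind `tiles = FALSE` but is not
used by any analysis here. Standard deviations are sample SDs
($n-1$) throughout, computed with a centred two-pass sum of squares so
constant windows give exactly zero; windows with fewer than two valid
cells are nodata, and block means never silently treat nodata as zero.

## Vegetation mapping

NDVI = (NIR − Red)/(NIR + Red). Because atmosphere and season shift the
whole NDVI distribution between campaigns, a classification threshold
is fitted per scene and never pooled: a Gaussian kernel density
(Silverman's bandwidth) is fitted to the scene's NDVI sample, modes are
kept when their topographic prominence is at least 5 % of the density
maximum, and the threshold is the arithmetic midpoint of the two most
prominent modes (sediment low, vegetation high). Fewer than two
prominent modes raises a typed error and the caller may supply a manual
threshold — the bandwidth and prominence floor are our choices, logged
in the threshold diagnostics, since only "peak analysis" is specified
by the field procedure. Classification is a strict `>` comparison, new
establishment is `late AND NOT early`, and nodata in either year
propagates so that incompletely observed cells never enter the at-risk
set. Externally supplied vegetation maps bypass the NDVI route.

## Micro-topography intensity, masking, calibration

Intensity is the tiled 10 m SD of the NIR band. Three exclusions are
applied before any statistic: vegetated cells; cells with zero skipped
percent (the mega-ripple zone below NHWL); and tidal creeks, detected
as slope > 3° **at 2 m resolution** and block-max resampled to 10 m so
that creek-adjacent cells fall out too. Two slope products therefore
exist — 2 m slope for creek detection, 10 m slope for every other
analysis — and are never interchanged.

The calibration of the image metric regresses log intensity on the log
SD of local slope in paired 10 m tiles (ordinary least squares),
dropping non-positive values with a logged count. In the package's
synthetic setting the paired tiles come from the pattern-bearing
sub-scene, mirroring a field calibration that surveys flats harbouring
patterns rather than featureless mud; on decoupled noise fields the
same regression yields an $R^2$ near zero, which is the negative
control.

## Estuary-scale statistics

* **Hypsometric curves**: over cells with positive skipped percent, the
  relative area (% of those cells) equalling or exceeding each observed
  value; non-increasing and starting at 100 %.
* **Annual trends**: OLS of the yearly mean (elevation, skipped
  percent, vegetated area) on year; cells vegetated in the first year
  or unobserved in any year are excluded first. Standard errors and
  95 % intervals are reported from three years; an exactly linear
  series has zero SE and a degenerate interval, handled explicitly.
* **Intensity by slope**: 120 logarithmically spaced bins, by default
  between 0.01° and 10°; per-bin mean, SE and count; empty bins keep
  missing statistics rather than zeros. When the curve's maximum is
  read off (tests, acceptance script), only bins with at least 10 tiles
  are considered — single-digit counts are under-replicated for a
  maximum, in the same spirit as the establishment surface's floor.
* **Establishment surface**: 85 linear intensity bins between 0 and the
  pooled 99.5th percentile (values above it are clamped into the top
  bin) × 101 unit-width skipped-percent bins centred on 0..100. The
  axis assignment and the intensity edges are our choices; only the
  85 × 101 shape is fixed by the reference analysis. Campaign pairs are
  pooled by **summing counts** before dividing — statistically coherent
  when pair sizes differ — with the unweighted mean of per-pair
  proportions available via `mode = "average"` for fidelity with
  descriptions that average arrays. Bins with fewer than 30 cells are
  missing, not zero, and are absent from the tidy output.
* **Indicator report**: a flat unit is flagged "approaching transition"
  in a year when (a) its mean skipped percent is positive, (b) its
  elevation trend is positive with the 95 % interval excluding zero
  (needs ≥ 3 years), and (c) its mean 10 m slope is below the 0.3°
  patterning boundary or declining toward it (negative slope trend with
  the interval excluding zero). Units are user-supplied crops or the
  whole scene.

## The drainage model

Bed: $S$ = linear ramp declining from top to bottom (drop per row
$100\,\Delta x \tan\theta$ cm) plus an autocorrelated noise field
generated by spectral synthesis (white Gaussian noise filtered by
$|k|^{-1.5}$, rescaled to mean 0 and sample SD exactly $\sigma_S$;
the amplitude exponent is configurable since the exact fractal recipe
is not pinned down). Water: $\partial W/\partial t =
\nabla\!\cdot\!\left(K W \nabla (W+S)\right)$ with $K = 1$; heights in
cm, cell size 1 m, no physical time calibration.

Numerical scheme (our design; only the equation and boundary offsets
are given by the source formulation):

* conservative finite-volume form; face flux $K\,W_{\mathrm{donor}}
  \,\Delta h$ with the donor the higher-free-surface cell;
* per-cell outflow limiting — outgoing fluxes are scaled so a cell
  cannot lose more water than it holds; the same limited transfer is
  applied antisymmetrically to donor and receiver, so mass is conserved
  to round-off and $W \ge 0$ always;
* adaptive step $\Delta t = 0.2\,\Delta x^2/(4 K \max W)$;
* down-slope boundary: offset-periodic wrap. The offset equals the ramp
  drop across the domain plus one row step, the unique value for which
  the wrapped gradient is exactly continuous and a uniform water layer
  on the noise-free ramp is an exact fixed point (both are tested).
  Lateral boundaries are plain periodic and carry no offset.
* initial depth $W_i = 0.1\,\sigma_S$, uniform; stop when the mean
  absolute per-cell change in water level **per unit model time** falls
  to $0.003\,W_i$, or at the step budget. We read the stop rule per
  unit time because the per-step reading is not invariant to the step
  size: the adaptive $\Delta t$ shrinks as water pools, which shrinks
  the per-step change and stops the run before the flow field is
  steady. The per-step reading remains available via
  `tol_mode = "per_step"`.
* the per-cell time average of $W$ is trapezoidal over the adaptive
  steps and includes the initial transient; flow concentration is the
  sample SD of that averaged field.

Problem sizes: the sweep analysed by the tests and the acceptance
script runs nx = 128 with 10 independently seeded surfaces per
inclination over {0.05, 0.25, 0.5, 1.0, 1.5}°, and the conservation
checks run at nx = 64 — a deliberately scaled-down version of a
512 × 512, 100-replicate experiment that the package can also run via
`slope_sweep(..., nx = 512, n_reps = 100)`.

## The synthetic estuary

The generator emulates the statistical structure the analysis assumes,
with known truth for recovery tests:

* **Tides**: M2 (12.42 h) + S2 (12.00 h) cosines, equal phase at
  $t = 0$, so the spring–neap envelope (beat period 14.77 d) is
  present; per-station amplification grows linearly along the axis
  (defaults 1 → 1.1); Gaussian gauge noise (default 2 cm); 30 days at
  10 min. Defaults give a 4 m spring and 2 m neap range — a macro-tidal
  NW-European setting.
* **DEM**: convex cross-shore profile
  $z(u) = z_{\mathrm{flat}} - (z_{\mathrm{flat}} - z_{\mathrm{chan}})
  u^{3}$ from +170 cm to −150 cm, flat anterior section high in the
  frame; uniform accretion (default 2 cm yr⁻¹, within the observed
  1–3 band) on the upper flat with a taper below mean water; static
  textures. Ridge–runnel texture: a 3 m quasi-periodic sinusoid whose
  phase drifts only over tens of metres, modulated by fractal noise,
  peak-to-trough relief ≤ 10 cm (default 6), planted only where the
  pre-texture slope is under the 0.3° ceiling and the cell reaches the
  NHWL zone within the simulated period; amplitude fades toward the
  slope ceiling and toward the zone edge, because abrupt texture edges
  would put spurious energy into the coarse 10 m slope field that real,
  gradually fading patterns do not have. Creeks: meandering incisions
  (60 cm deep, ~1 m half-width) whose walls exceed 3° at analysis
  resolution. Mega-ripples (25 m, 15 cm) only in the zone that stays
  below NHWL throughout.
* **Orthophotos**: NIR = base − wetness darkening (scaled by
  $1 - \mathrm{skipped}/100$) + 0.015 × local elevation anomaly (cm;
  the anomaly is the DEM minus its ~2-wavelength box blur, so uniform
  gradients carry no signal) + sensor noise (SD 0.005). Per-cell NDVI
  targets are drawn from a bimodal mixture (sediment 0.10, vegetation
  0.50, SD 0.05) and the Red band is solved from NIR and the target, so
  classification truth is exact.
* **Vegetation**: per interval, each bare cell establishes with
  $p = \mathrm{logit}^{-1}(\beta_0 + a\,\mathrm{skipped}\% +
  b\,\mathrm{intensity})$, forced to zero where skipped = 0; defaults
  $\beta_0 = -8$, $a = 0.06$ per percent, $b = 40$ per intensity unit —
  the simplest monotone surface with the required zero boundary and a
  diagonal establishment edge. Vegetation persists once established
  (the analysis measures establishment, not dieback). The Bernoulli
  draws happen at the 10 m analysis resolution and use exactly the
  exposure and intensity rasters the downstream analysis sees, so
  binned recovery is a clean binomial check.

What the generator does **not** emulate: hydrodynamics and sediment
transport, waves and ship wakes, seasonal NDVI phenology, atmospheric
effects, georeferencing error between campaigns, and any biogeomorphic
feedback of vegetation on accretion. Passing recovery tests on this
synthetic world therefore demonstrates that the *analysis chain* is
correct and unbiased under its own assumptions — not that those
assumptions hold in any particular estuary.

The demonstration scenario (`run_demo()`) uses two 240 × 240 m scenes
over 2004–2013: a transition flat starting just below NHWL (88 cm) and
accreting at 2.5 cm yr⁻¹ through it (establishment intercept −5 so
colonisation is observable within the decade; no creeks, calm 1 cm
gauge noise), and a static control with a uniform ~0.76° slope. Because
establishment is impossible while the whole flat sits below NHWL, and
the indicator can fire in the first year the flat pokes above it (given
three years of trend), the flag structurally precedes the first
establishment on the rising flat; the control can never satisfy the
accretion condition.

## Reproducibility and limitations

All randomness flows from one root seed through named substreams
(`derive_seed()`), so identical configurations give bit-identical
scenes, simulations and pipeline outputs; the pipeline writes a
provenance log with input hashes and the seed.

Known limitations: the NDVI route cannot separate fibrous epibenthic
macroalgae from vascular vegetation; the intensity metric is
shift-invariant but not scale-invariant, so uncalibrated digital
numbers change its absolute scale (the calibration fit absorbs this);
no reprojection is provided — inputs must be co-registered; the
drainage model makes no claim about the decline of patterning at the
very lowest slopes, which lies outside what this diffusion mechanism
can produce; and the indicator thresholds (0.3°, the 95 % trend
interval) are tuned to macro-tidal European estuaries and should be
revisited before use elsewhere.
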