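---
title: "Methods: hexagon-binned richness and the upwelling association model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hexagon-binned richness and the upwelling association model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The analysis in one paragraph

Per-fix tracking records from many species and colonies are binned into a
gap-free grid of equal-area hexagons (200 km corner-to-corner). Relative
species richness per cell — the number of study species with at least one
fix there — is the response of a penalized additive model with smooth terms
for sea-surface temperature, log10 chlorophyll *a*, a 2-D spatial smooth of
the projected cell coordinates, and a null-usage covariate expressing what
usage would look like under habitat availability and sampling effort alone.
Candidate term sets are ranked by AIC; the fitted SST smooth is read for
the temperature at which richness peaks; residual variograms check the
independence assumption. Alongside the modelling, per-individual and
per-species overlap statistics with a focal region polygon (an upwelling
system) quantify how widely that region is shared across species.

## Grid geometry

*Diameter.* The hexagon "diameter" is read as the corner-to-corner
circumdiameter, so a 200 km grid has side (= circumradius) 100 km and
projected cell area (3√3/2)·100² = 25 980.76 km². This is a documented
constant, configurable via `circumdiameter_km`; the flat-to-flat reading
would give cells 15% smaller in linear scale.

*Projection.* Hexagons are regular only in a plane, so the grid lives in a
spherical Lambert azimuthal equal-area projection centred mid-Atlantic at
(15° W, 0° N). Equal-area is the property that matters — every cell covers
the same ocean area exactly, so richness counts are comparable across
cells. Shape distortion grows away from the centre (noticeable poleward of
~60°); results at high latitude are projection-sensitive, which is why the
projection centre is exposed in `laea_projection()`.

*Assignment.* Points are assigned to cells by cube-rounding of fractional
axial lattice coordinates, an exact O(1) method; the test suite verifies it
against brute-force nearest-centre search, which is equivalent for a
hexagonal lattice. Points exactly on a cell edge (a measure-zero set)
resolve deterministically by the rounding rule. Longitudes are normalised
to [−180, 180); Atlantic-style domains only, no antimeridian crossing, no
polar caps.

*Ocean mask.* An optional land polygon flags cells whose centre is on land;
those cells are excluded from null-usage surfaces and model design tables.
Fitting and evaluating the spatial smooth on ocean cells only is this
package's stand-in for a boundary-respecting (soap-film-style) smoother:
it prevents the model from being informed by land cells, though unlike a
true soap film it does not prevent smoothing *across* a land barrier.
That is a known limitation for narrow peninsulas.

## Overlap statistics

"Proportion of time in region" is computed as the proportion of fixes
inside the region polygon, each fix equally weighted — appropriate for an
equal-cadence (two fixes/day) light-logger regime, and simpler than
time-weighted interpolation. An individual "visits" the region when it has
at least one fix inside (`min_fixes_visit` raises this threshold). The
winter period is the span between an individual's first and last analysed
fix. Species summaries report means ± sample s.d. (n−1); a single-bird
species has an undefined s.d., reported as 0 and flagged by `sd_defined`.
Containment is even-odd ray casting with boundary points counting as
inside; holes are supported.

## Null usage

The null-usage covariate combines the two stated ingredients —
availability and effort — in the most transparent form available: for each
ocean cell, the sum over colonies of `n_tracked · exp(−d/range_scale_km)`
with `d` the great-circle distance from colony to cell centre, normalised
to sum to 1. The kernel family and range scale (default 1500 km) are
deliberately config-exposed: of all the analysis components this is the
least constrained by published detail, and conclusions should be checked
against other kernels. Scaling all sample sizes by a constant leaves the
surface unchanged; only relative effort matters.

## The additive model

*Family.* Gaussian/identity on richness counts by default, matching
adjusted-R² reporting; richness is a small count, so Poisson/log is
available via `family` and worth running as a sensitivity.

*Bases.* Thin plate regression splines, basis dimension `k = 10` for 1-D
smooths (a maximum of 10 knots, superfluous ones penalized away) and
`k_xy = 30` for the 2-D spatial smooth, fitted by `mgcv`. The spatial
basis is intentionally moderate: its job is to absorb broad-scale spatial
structure (multi-thousand-km trends), not to compete with the
environmental terms for the features they explain.

*Smoothness selection.* REML with mgcv's double penalty (`select = TRUE`)
by default. GCV is available, but on these data the environmental
covariates are themselves smooth functions of space, and weakly determined
null-space components of one smooth can be traded against another
(concurvity); the double penalty shrinks such components and gives more
stable partial effects.

*Model frame.* The design table is restricted to ocean cells within the
latitudinal envelope of the observed fixes (±2°, `lat_envelope_pad_deg`).
Cells poleward of every observed location are outside the tracked
populations' sampled range: they carry no information about *relative*
richness of the tracked set, but thousands of structurally empty far-field
cells give concurvity trades a long lever arm. Whether the original
analyses screened cells by effort is not documented; this screen is this
package's explicit design choice, and disabling it (`NULL`) is supported.

*Selection.* All non-empty subsets of {SST, CHL, XY, null} are fitted and
ranked by AIC computed with effective degrees of freedom (+1 for the
Gaussian scale parameter). The reported table shows models within 6 ΔAIC;
the *retained* model is the most parsimonious model within 2 ΔAIC of the
best — equivalently, a term is kept only when its inclusion improves AIC
by more than 2. AIC ties below 10⁻⁶ rank the smaller-d.f. model first.

*Reading the optimum.* `smooth_peak()` evaluates the centred smooth on a
200-point grid over the observed covariate range and returns its highest
*interior mode* (turning point), with the contiguous interval of grid
points whose estimate lies within 2 pointwise s.e. of the peak. An
environmental optimum is a turning point by definition; monotone runs into
the extremes of the covariate range — where data are sparse and the
partial effect is weakly determined — are not read as optima. When the
fitted effect is monotone over the whole observed range, the boundary
argmax is returned (a monotone response genuinely has its maximum at the
range end).

*Diagnostics.* VIF (1/(1−R²) from auxiliary linear regressions; < 3 read
as acceptable) screens the covariates; the residual variogram bins
semivariance up to half the maximum pairwise distance and compares it with
a per-bin min/max envelope over 99 random permutations of residuals across
locations (a subsample cap of 1500 points keeps the O(n²) pair work
bounded).

## The synthetic-study generator

The generator's role is to produce data with the statistical structure the
analysis assumes, plus a truth record, so every downstream stage is
testable. What it emulates, and the defaults:

- **Sampling.** Two fixes per day (the two twilights of a light-logger
  day); fixes within ±10 days of 21 March and 23 September are dropped
  (latitude is unresolvable near equinoxes); zero-mean Gaussian location
  error with s.d. 0.7° longitude and 1.5° latitude (published geolocator
  error scales; latitude error dominates).
- **The cohort.** The full-scale configuration has 8 species from 12
  colonies spanning 75° N to 62° S, 123 individuals, winter periods of
  roughly 90–290 days, and per-species region-visit probabilities and
  region-time fractions patterned on the bundled published summary table.
- **Environment.** SST is a meridional baseline (28 °C at the equator,
  −0.3 °C per degree latitude) with a zonal tilt (−0.08 °C per degree
  eastward; eastern boundaries are cooler than western at the same
  latitude) plus mesoscale noise (s.d. 1.5 °C, 5° correlation scale) and a
  −4.2 °C anomaly inside the upwelling polygon, which places the region's
  SST near 17.5 °C. CHL is log-normal, multiplied by 5 inside the region.
  The zonal tilt and mesoscale noise matter: without them SST degenerates
  to a pure function of latitude, which real satellite climatologies are
  not, and an SST effect would be inseparable from any spatial smooth.
  Fields are missing over the continental land mass east of the upwelling.
- **Movement and settlement.** Each individual draws a winter duration and
  a Bernoulli region-visit decision. Wintering sites follow a thermal
  suitability kernel centred on `sst_optimum` (17.5 °C, s.d. 2 °C) — this
  is what *generates* a richness optimum at that temperature. Visiting
  individuals open the winter with a stint centred in the region (a
  Beta-distributed fraction of the winter around the species mean:
  anything from brief staging to full residence), then relocate to one of
  their cohort's shared secondary aggregation sites; non-visitors go
  straight to a site. Sites are drawn with the same thermal weight, so
  different cohorts coincide preferentially where SST is near the optimum
  — multi-species hotspots at the right temperature emerge at spatially
  separated locations in both hemispheres, which is exactly the repeated
  association that identifies an SST effect against a spatial smooth.
  Movement is a discrete-time biased random walk toward the current
  centroid (step noise 120 km/day, attraction 0.25/day); tracks start in
  the walk's stationary spread around the first centroid, so they
  represent the stationary winter period the analysis window covers
  (`start = "colony"` instead includes the outbound migration leg).
- **Truth.** Pre-error positions drive the truth record (region membership
  and proportions), so the pipeline's robustness to location error is
  measurable; the generated SST optimum is recorded for recovery checks.

What it does **not** emulate: light-curve simulation or threshold
geolocation (error is injected directly), behaviourally realistic movement
(area-restricted search, wind drift), seasonal turnover of the richness
surface within the winter, real coastline geometry, and any correlation
between CHL and settlement beyond the shared region. Passing end-to-end
tests therefore demonstrate that the pipeline recovers the structure this
generator creates — they do not certify performance on real tracking data,
where winter-period definitions, device failure and species-specific
migration phenology add variation the generator lacks.

## Test and check scales

The unit suite runs compact studies (3–5 species, 2–8 birds per cohort,
30–90-day winters, ~1500-cell grids). End-to-end recovery checks use the
full-scale 123-bird configuration on its 90° × 141° domain (~6000 cells,
~3900 modelled after screening) across 10 seeds; selection-consistency and
false-inclusion calibrations run on design-level simulations (600 and 250
rows) where the generating effects are known exactly. These sizes are the
package's chosen compromise between statistical resolution and a test
suite that runs in minutes.

## Known limitations

- The spatial smooth does not respect land barriers (see above).
- Richness is relative to the tracked species set and uncorrected for
  effort differences beyond the null-usage covariate; no
  rarefaction/coverage standardisation.
- The null-usage formulation is a transparent stand-in; its kernel and
  scale materially shape that covariate.
- The SST–space concurvity that motivates the REML/double-penalty default
  and the interior-mode peak reader is intrinsic to modelling a mapped
  covariate alongside a spatial smooth; partial effects should always be
  read together with `mgcv::concurvity()` on real data.
- Equal fix weighting assumes the device's cadence; resampling is advised
  for mixed-device studies.
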