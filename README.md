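# hexrich

Macroecological analysis of multi-species animal tracking data: where do
migratory marine predators pile up, and what ocean conditions drive it?

`hexrich` implements the full analysis chain used to link pan-Atlantic
seabird tracking data to an eastern-boundary upwelling system such as the
Canary Current: equal-area hexagon binning of location fixes, relative
species-richness surfaces, region-overlap statistics, accessibility-based
null-usage surfaces, and penalized additive modelling of richness against
sea-surface temperature (SST), chlorophyll *a* (CHL), spatial position and
null usage. It is aimed at movement ecologists who have per-fix tracking
tables (e.g. from light-logger geolocators), a region polygon, and gridded
environmental climatologies, and who want the species-community view rather
than single-animal home ranges.

A seeded synthetic-study generator (tracks with geolocator-scale error and
equinox gaps, SST/CHL fields with a cool productive upwelling, a truth
record) makes the whole pipeline testable end to end without any satellite
or archival-tag downloads.

## The model

Fixes are binned into a gap-free tiling of regular hexagons with 200 km
corner-to-corner diameter, built in a Lambert azimuthal equal-area
projection so every cell has projected area (3√3/2)·100² ≈ 25 980.76 km².
Relative species richness in cell *i* is the number of study species with
at least one fix there. The association with the environment is a penalized
additive model

&nbsp;&nbsp;&nbsp;&nbsp;richness_i = β₀ + f₁(SST_i) + f₂(log₁₀ CHL_i) + f₃(X_i, Y_i) + f₄(null_i) + ε_i

with thin plate regression splines (basis dimension 10 for 1-D terms),
smoothness chosen by REML with a double penalty, fitted on ocean cells
only. Null usage is the expected usage under habitat availability and
colony sampling effort alone: a distance-decay accessibility kernel,
weighted by per-colony sample size, normalised over ocean cells. Candidate
term sets are ranked by AIC (all subsets); terms are retained when their
inclusion improves AIC by more than 2. The SST optimum is read off the
fitted smooth as its highest interior mode with a ±2 s.e. interval, and
residual variograms with permutation envelopes check that no spatial
autocorrelation is left.

## Worked example

Simulate a compact five-species study (30 birds, north-east Atlantic,
thermal optimum at 17.5 °C inside the upwelling region), grid it, and look
at richness and region use:

```r
library(hexrich)

cross_species_stats(atlantic_tracking_summary())
#> # A tibble: 1 × 3
#>   n_species mean_pct_visiting sd_pct_visiting
#>       <int>             <dbl>           <dbl>
#> 1         8              76.6            28.1

cfg  <- demo_study_config(seed = 1)
st   <- simulate_study(cfg)
st
#> synthetic_study: 30 individuals, 5 species, 6630 fixes; true SST optimum 17.50 degC

grid <- set_ocean_mask(build_hex_grid(cfg$domain), st$land)
grid
#> hex_grid: 1518 cells, circumdiameter 200 km (side 100 km), area 25980.76 km2/cell
#>   domain lon [-45, 5], lat [-10, 50]; 1217 ocean cells

rich <- relative_richness(occupancy(st$tracks, grid), grid)
dplyr::arrange(rich, dplyr::desc(richness))[1:3, ]
#> # A tibble: 3 × 7
#>    cell     x     y   lon   lat ocean richness
#>   <int> <dbl> <dbl> <dbl> <dbl> <lgl>    <int>
#> 1   714  86.6  1950 -14.2  17.6 TRUE         5
#> 2   746   0    2100 -15    19.0 TRUE         5
#> 3   779 -86.6  2250 -15.8  20.3 TRUE         5
```

All five species co-occur only in cells inside the upwelling region
(around 18–20 N on the 15 W meridian). Species-level region use mirrors the
configured visit probabilities:

```r
tab <- species_table(st$tracks, st$region)
print(tab[, c("species", "n", "pct_visiting", "proportion_mean")], digits = 2)
#> # A tibble: 5 × 4
#>   species                      n pct_visiting proportion_mean
#>   <chr>                    <int>        <dbl>           <dbl>
#> 1 Cory's shearwater            6         33.3          0.0422
#> 2 Scopoli's shearwater         6        100            0.386
#> 3 common tern                  6        100            0.179
#> 4 lesser black-backed gull     6         83.3          0.175
#> 5 northern gannet              6         83.3          0.377
```

The one-command pipeline (`run_pipeline(pipeline_config(...))`) chains
simulation or file input, gridding, overlap, richness, covariates, null
usage, VIF screening, AIC selection, smooth-peak inference and the residual
variogram, and writes every artifact (CSV/GeoJSON/JSON, each stamped with a
configuration hash) to an output directory. `autoplot()` methods draw the
richness map, the fitted SST response with its peak interval, and the
variogram; `tidy()`/`glance()` summarise fitted models.

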