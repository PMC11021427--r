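# habscape

Habitat quality and landscape-pattern dynamics on categorical rasters.

`habscape` is an R package for studying how land-use / land-cover (LU/LC)
change reshapes habitat quality in semi-arid watershed landscapes. It
implements, as one tested pipeline:

* a **seeded synthetic-landscape generator** — seven-class categorical maps
  (Zagros forest, rangeland in good / fair / poor condition, water,
  agriculture, built-up) with controllable patch clumping, binary threat
  layers, NDVI surfaces, and temporally evolving map pairs — so every
  downstream stage is testable without satellite data;
* an **InVEST-style habitat-quality model** driven by distance-decaying
  threat kernels;
* **Markov land-change analysis**: transition-matrix estimation between two
  dated maps, demand projection, and suitability-ranked spatial allocation
  of the projected change;
* **landscape-pattern metrics** (NP, PD, SHDI, CONTAG) with FRAGSTATS
  conventions, and tile-wise Pearson correlation of mean habitat quality
  against those metrics;
* classification-accuracy statistics (overall accuracy, Cohen's kappa,
  Cramer's V driver screening, NDVI condition thresholds).

## The model

Quality of cell *x* with land type *j* follows the half-saturation
transform

```
Q_xj = H_j * (1 - D_xj^z / (D_xj^z + K^z))
```

where `H_j ∈ [0, 1]` is the habitat suitability of type *j* (built-up is
non-habitat, `H = 0`), `K` the half-saturation constant and `z` a sharpness
exponent (default 2.5). Degradation accumulates over threats *r* and threat
cells *y*:

```
D_xj = Σ_r Σ_y (w_r / Σ w) · r_y · i_rxy · β_x · S_jr
```

with distance decay `i = 1 - d/d_max` (linear) or `i = exp(-2.99 d/d_max)`
(exponential, clamped to 0 beyond the maximum effective distance `d_max`).
The seven shipped threat parameterizations (agriculture 8 km / weight 0.82 /
linear, livestock grazing 6 / 0.72 / linear, urban 8 / 0.31 / exponential,
rural 8 / 0.51 / exponential, mining 10 / 0.69 / exponential, main roads
7 / 0.50 / linear, minor roads 5 / 0.50 / linear) and the class × threat
sensitivity table are expert-elicited values for a central-Iranian watershed,
shipped as CSV defaults and overridable. The spatial double sum is evaluated
exactly by FFT convolution and is verified in the tests against a literal
double-sum oracle to 1e-6 relative error.

## Worked example

```r
library(habscape)

cfg <- synthetic_config(n_rows = 64, n_cols = 64, seed = 7)
lc  <- generate_landcover(cfg)        # seven-class clumped landscape
th  <- generate_threat_layers(lc, cfg) # the seven binary threat layers
hq  <- habitat_quality(lc, degradation(lc, th))
hq
#> <hs_quality: 64 x 64, K = 215.5, z = 2.5, mean Q = 0.1731>
glance(hq)
#> # A tibble: 1 × 5
#>   mean_q mean_d     k     z n_valid
#>    <dbl>  <dbl> <dbl> <dbl>   <int>
#> 1  0.173   326.  215.   2.5    4096
metrics_report(lc)
#> # A tibble: 1 × 4
#>      np    pd  shdi contag
#>   <int> <dbl> <dbl>  <dbl>
#> 1    39  10.6  1.76   43.1
classify_hq(hq)$areas
#> # A tibble: 6 × 4
#>   level name            n_cells area_ha
#>   <int> <chr>             <int>   <dbl>
#> 1     0 No habitat          205   18.4
#> 2     1 Poor               2939  265.
#> 3     2 Relatively poor     870   78.3
#> 4     3 Moderate             82    7.38
#> 5     4 Relatively good       0    0
#> 6     5 Good                  0    0
```

Mean quality is 0.173: with every threat active and the half-saturation
constant set automatically to half the maximum landscape degradation, most
cells of this small, threat-dense landscape fall in the "Poor" band — the
landscape totals 368.64 ha of which 265 ha are Poor and only 7.4 ha
Moderate; the 18.4 ha of built-up land are non-habitat by definition. The
four pattern metrics say the 64×64 map holds 39 patches (10.6 per 100 ha),
mixes its seven classes diversely (SHDI 1.76 of a possible ln 7 ≈ 1.95) and
is moderately aggregated (CONTAG 43.1%).

The full three-date study — generate a 1991 map, evolve it to 2021 under a
degradation transition matrix, project 2051 by a one-step Markov chain with
suitability-ranked allocation, score habitat quality per date and correlate
it with per-tile pattern metrics — runs with

```r
res <- run_pipeline(scenario_config(), "out_dir")
res$mean_hq        # declining mean quality across the three dates
res$correlation    # tile-wise HQ-vs-metric Pearson r (per date and pooled)
```

or from a shell via `Rscript inst/cli/habscape.R run-all --config cfg.yaml
--out out_dir`.

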