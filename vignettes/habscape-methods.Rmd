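---
title: "habscape: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{habscape: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`habscape` links four pieces of landscape ecology — land-cover change,
threat-driven habitat degradation, pattern metrics, and their correlation —
into one seeded, fully testable pipeline. This vignette documents the
models it implements, the conventions it fixes where the literature leaves
room, and the reasoning behind the genuinely open design choices.

## 1. The habitat-quality model

Habitat quality is a per-cell score in $[0,1]$ expressing the capacity of
the environment to support species persistence; 0 means non-habitat. The
model combines three ingredients.

**Distance decay.** A threat of kind $r$ present in cell $y$ degrades a
cell $x$ at distance $d_{xy}$ (Euclidean, between cell centres, metres)
with intensity

$$i_{rxy} = 1 - d_{xy}/d_{r,\max} \quad\text{(linear)} \qquad
  i_{rxy} = \exp(-2.99\, d_{xy}/d_{r,\max}) \quad\text{(exponential)}.$$

The linear kernel reaches zero exactly at the maximum effective distance
$d_{r,\max}$. The exponential kernel does not, so it is clamped to zero
beyond $d_{r,\max}$: the table parameter is a *maximum effective* distance
and influence beyond it is cut. The clamp is a convention, documented here
and asserted by the locality tests.

**Degradation.** For cell $x$ of land type $j$,

$$D_{xj} = \sum_{r=1}^R \sum_{y=1}^{Y_r}
  \frac{\omega_r}{\sum_r \omega_r}\, r_y\, i_{rxy}\, \beta_x\, S_{jr},$$

where $\omega_r$ is the threat weight, $r_y \in \{0,1\}$ the binary threat
presence, $\beta_x$ cell accessibility (default 1) and $S_{jr}$ the
sensitivity of type $j$ to threat $r$. Note the inner sum is **not**
normalized by the number of threat cells $Y_r$: the double sum is evaluated
exactly as written, so $D$ scales with threat abundance and is typically
$\gg 1$ on threat-dense landscapes. The automatic half-saturation choice
below absorbs that scale. Weight normalization makes $D$ invariant to
uniform rescaling of all $\omega_r$ (a tested property).

**Half-saturation transform.**

$$Q_{xj} = H_j \left(1 - \frac{D_{xj}^z}{D_{xj}^z + K^z}\right),$$

with habitat suitability $H_j$, half-saturation constant $K$ and exponent
$z$. $Q = H_j$ at $D = 0$, $Q = H_j/2$ at $D = K$, and $Q \equiv 0$ for
non-habitat ($H_j = 0$, the built-up class). Closed forms the acceptance
tests assert exhaustively over the shipped tables.

### Parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| $d_{r,\max}$, $\omega_r$, decay kind | km, –, – | shipped `threats.csv` | expert-elicited values for a semi-arid central-Iranian watershed |
| $S_{jr}$, $H_j$ | – | shipped `sensitivity.csv` | same elicitation; built-up $H=0$ |
| $z$ | – | 2.5 | the customary value of the InVEST implementation |
| $K$ | same scale as $D$ | `"auto"` = max$(D)$/2 | InVEST guidance; with the unnormalized double sum, $D$'s scale is landscape-dependent, so a fixed constant would be arbitrary |
| $\beta_x$ | – | 1 | no accessibility data in the synthetic setting |
| cell size | m | 30 | Landsat-class resolution the parameter tables were elicited for |

In the multi-date pipeline, $K$ is resolved **once, on the baseline date's
degradation surface**, and reused for later dates. Resolving it per date
would rescale every map to its own maximum and make mean quality
incomparable across dates — the trend over time is precisely what the
study design wants to read.

Because `"auto"` ties $K$ to the realized maximum of $D$, absolute quality
levels are comparative, not physical: a landscape with every threat layer
active sits mostly below $Q = 0.2$. Conclusions should be drawn from
contrasts (between dates, between tiles), never from the absolute level —
the same caveat the original model carries.

### Numerical evaluation

The inner spatial sum is a convolution of the binary threat raster with the
decay kernel; it is evaluated by zero-padded FFT. The kernel is cropped to
the grid extent (no two in-grid cells are farther apart than the grid
diagonal), negative FFT round-off is clamped at zero, and the tests require
agreement with a literal double-sum oracle to $10^{-6}$ relative error on
seeded fixtures. No padding beyond the grid is applied: threats outside the
study area do not exist, so degradation is biased low near the border —
the study-area "dummy border" caveat of the original model, reproduced
deliberately.

## 2. The synthetic-landscape generator

The generator replaces classified satellite imagery; it is first-class,
tested code, not a fixture. A seeded uniform white-noise field is smoothed
with an isotropic Gaussian kernel of radius `clumping` (cells; edge mass
renormalized) and classes are assigned by slicing the sorted field at the
cumulative target proportions (largest-remainder rounding), so achieved
composition matches the targets to within one cell and `clumping = 0`
yields spatially independent cells. This smoothed-noise quantile slicing
was chosen over published neutral-landscape algorithms because the only
contract downstream is *controllable fragmentation* — NP falls and CONTAG
rises monotonically in `clumping`, which the tests check — and it is
trivially seeded and dependency-free.

Default composition (forest 0.20, rangeland good/fair/poor 0.25/0.22/0.15,
water 0.02, agriculture 0.11, built-up 0.05) gives habitat classes 82% of
the landscape — a baseline habitat share typical of the semi-arid
watersheds the generator emulates before recent agricultural expansion.

Threat layers derive deterministically from land cover: agriculture cells,
the three rangeland classes (a proxy for livestock grazing — how grazing
was spatialized in the source study is unstated, so the simplest
class-based proxy is used), and built-up cells split into urban (largest
8-connected component) versus rural (the rest) — any deterministic split
serves, since the two threats differ only in their parameter rows. Mines
are seeded random cells outside water; roads are seeded random
boundary-to-boundary Bresenham polylines one cell wide, fixed across dates
within a scenario (roads persist; agriculture and grazing move with the
land cover).

NDVI surfaces draw rangeland cells from class-conditional truncated
normals — means 0.22 / 0.145 / 0.06, sd 0.01, truncated to the condition
intervals good $(0.17,\infty)$, fair $[0.12, 0.17]$, poor $[0.01, 0.12)$ —
so re-thresholding recovers the generating class. The published intervals
touch at 0.12 and 0.17 without a boundary convention; here lower bounds are
inclusive and upper bounds exclusive, except fair which is closed at 0.17
(good is open above it). Values below 0.01 map to a non-rangeland code.

**What the generator does not emulate:** classification error, mixed
pixels, topographically conditioned land cover, river networks, real road
topology, spatially autocorrelated NDVI noise. Passing tests therefore
demonstrate the *internal* correctness and the qualitative behaviour of the
methods, not agreement with any real landscape.

## 3. Land-change analysis

Transition matrices are estimated by cross-tabulating two dated maps over
the full legend and row-normalizing; a class absent at the first date gets
an identity row (it persists by convention rather than producing `NaN`).
Composition is projected forward as $v^\top P^n$; one step spans the
matrix's calibration period. The projection to the third date uses **one**
30-year step of the matrix estimated from the first 30-year period:
annualizing via matrix roots is ill-posed for many empirical matrices, and
the calibration and projection horizons are equal here anyway.

Spatial allocation of projected change replaces the transition-potential
neural network of TerrSet-style workflows — deliberately. That network is
upstream machinery the correlation study merely consumed, and an opaque
learner would add nothing testable to a synthetic pipeline. Instead,
per-transition integer targets come from largest-remainder rounding of the
expected counts within each donor class (donor totals conserved exactly,
every transition within one cell of expectation — asserted exhaustively),
and the highest-suitability donor cells convert first, ties broken by a
seeded shuffle. Suitability surfaces are min–max-normalized weighted sums
of covariates (constant covariates contribute a uniform 0.5; all-zero
weights give a uniform surface), defaulting to uniform when no covariates
are supplied.

Driver screening bins each continuous covariate into deciles (quantile
breaks; covariates with few distinct values use those values as categories
directly), cross-tabulates against the binary change mask, and flags
Cramer's V > 0.15. Deciles are a determinism choice — the convention used
when published V values for continuous covariates omit the binning rule.
Note the chance level of decile-binned V is roughly $\sqrt{9/n}$, so
screening is only meaningful with a few thousand cells or more.

## 4. Landscape metrics

Conventions (all FRAGSTATS defaults, exposed as arguments where sensible):
patches are 8-neighbour connected components of same-class cells, with
nodata splitting patches; adjacencies for contagion are 4-neighbour pairs,
each counted once in each direction, pairs touching nodata excluded; patch
density is patches per 100 ha of valid area; SHDI is $-\sum P_i \ln P_i$ in
nats. CONTAG is

$$\mathrm{CONTAG} = 100\left(1 + \frac{\sum_{i,k} p_{ik}\ln p_{ik}}
 {2\ln m}\right), \qquad p_{ik} = P_i\, \frac{g_{ik}}{\sum_k g_{ik}},$$

over the $m$ classes present, returning an explicit `NA` marker at $m = 1$
(where the index is undefined, not 100).

One structural property of this formula deserves a note: since each row of
$p$ sums to $P_i$, the entropy of $p$ is at least the entropy of the class
proportions, so CONTAG is capped at
$100\,(1 - H(P)/(2\ln m)) \le 50 + 100\,(\ln m - H(P))/(2 \ln m)$.
For two balanced classes the ceiling is exactly 50: two homogeneous
half-planes approach 50 from below as the boundary fraction vanishes, and
the checkerboard sits at exactly 50 as well (perfectly *predictable*
adjacency, albeit unlike). High absolute CONTAG therefore requires
unbalanced composition, not just aggregation; within fixed proportions,
CONTAG still orders landscapes by aggregation, which is how the correlation
analysis uses it.

All four metrics are verified against brute-force oracles (queue flood
fill, explicit pair enumeration) on small seeded fixtures.

## 5. The correlation study

Published correlations of habitat quality with pattern metrics rarely
state their analysis unit. Here the landscape is partitioned into square
tiles (default 16×16 cells; trailing strips narrower than a quarter tile
merge into their neighbours, which on fully valid rasters equals a
25%-valid-cell keep rule), each tile contributes mean quality plus its own
metric bundle, and Pearson $r$ with a two-sided $t$-test $p$ ($n-2$ df) is
reported per metric — per date and pooled over dates; tiles with undefined
CONTAG are dropped pairwise with the retained count reported. The 0.05
significance level is reported without multiple-testing correction,
matching the practice being emulated. Zero-variance inputs return an `NA`
marker rather than an error.

The package's qualitative headline is a *sign* structure: under
fragmentation-driven degradation, tile quality correlates positively with
CONTAG and negatively with NP, PD and SHDI. `sign_recovery()` runs
replicated scenarios — clumped baseline, scattered conversion of habitat to
agriculture and built-up over three dates — and records the pooled
correlation signs and the per-date mean quality. The acceptance suite
requires the NP and CONTAG signs in at least 95% of 20 replicates and a
monotone quality decline in all of them. Absolute $r$ magnitudes are *not*
targets: they depend on the correlation unit chosen and on real spatial
structure the generator does not emulate.

## 6. The pipeline and reproducibility

`run_pipeline()` chains: baseline generation → stochastic evolution under
the historical matrix (default: a matrix moving the 82% habitat share to
roughly two thirds in one step and roughly half in two, emulating the
published trajectory) → transition estimation → Markov projection with
ranked allocation → threat derivation, degradation and quality per date
($K$ from the baseline) → six-level classification (exactly 0 = "No
habitat", then half-open 0.2-wide bands; areas conserve the valid area) →
net change (sums to zero on fully valid maps) → metrics, per-tile
statistics and correlations. Every stage failure is re-raised with a stage
label.

A master seed drives everything; per-stage seeds are derived by hashing the
stage name with the master seed (all within 32-bit range), so stages are
individually reproducible and two runs of the same configuration produce
byte-identical CSV tables — a tested guarantee. Rasters are written as
plain-text ESRI ASCII grids (lossless for values, nodata and
georeference); single-band TIFF is supported for integer-coded and
unit-interval rasters.

Problem sizes: the default scenario is a 128×128 grid (368.64 ha at 30 m)
with 16-cell tiles; oracle-equivalence checks run on fixtures up to 32×32,
metric oracles up to 16×16, and the replicated sign experiment uses 20
scenarios at the default size. These sizes give the law-of-large-numbers
checks comfortable tolerances (binomial ±0.03 on a transition probability
at ~8k donor cells) while keeping the whole suite fast.

## 7. Known limitations

* Absolute quality levels depend on the auto-scaled $K$ and the
  unnormalized degradation sum; only contrasts are interpretable.
* Border cells are under-degraded (no outside-the-grid threats).
* The allocation rule is a deterministic stand-in for transition-potential
  modelling; it conserves demand but does not learn spatial drivers.
* The generator's landscapes are statistically, not physically, realistic;
  no claim about any real watershed follows from the shipped defaults.
* Habitat rarity, monetary valuation and class-level metric suites are out
  of scope.
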