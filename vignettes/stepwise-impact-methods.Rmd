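---
title: "Step-wise modelling of invasive-wasp impacts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-wise modelling of invasive-wasp impacts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepimpact)
options(stepimpact.quiet = TRUE)
```

## The model

`stepimpact` estimates where an invasive paper wasp can live, how many
nests it builds there, and how much prey those nests remove in a season.
The three layers multiply through in a step-wise chain, each one masking
or scaling the next:

1. **Distribution.** A presence-only species distribution model relates
   occurrence records to six environmental layers (elevation, degree days
   at a 10 °C base, annual rainfall, solar radiation, max/min annual
   temperature) on a 500 m (25 ha) grid. The continuous suitability surface
   is thresholded into a suitable/unsuitable mask.
2. **Density.** Nest density $D_c$ (nests/ha) and occupancy $\psi_c$ (the
   fraction of 10 × 10 m plots holding at least one nest) are estimated per
   land-cover class from plot surveys, assigned nominally (3 nests/ha,
   $\psi = 0.03$) for low-preference classes, and set to zero for
   unsuitable ones. Class areas $A_c$ inside the suitable mask give the
   national table: occupied area $\lfloor A_c \psi_c \rfloor$ and total
   nests $\lfloor A_c \psi_c D_c \rfloor$.
3. **Foraging intensity.** The foraging success rate
   $F = 60\,r\,m\,q$ (prey nest⁻¹ h⁻¹) multiplies the forager return rate
   $r$ (min⁻¹), the fraction of returns carrying material $m$, and the
   fraction of material that is prey $q$. Seasonal foraging time is the
   count of February–April bright-sunshine hours per cell. Per-pixel
   impact is then
   $\text{prey} = (25\,\psi_c\,D_c)\; F \; \text{hours}$, zero outside the
   suitable mask.

## The distribution model

The fit maximizes the penalized presence/background log-likelihood

$$\ell(\beta) = \frac{1}{n_p}\sum_{p}\beta^\top f_p \;-\;
  \log \sum_{b}\exp(\beta^\top f_b)\;-\;\lambda\lVert\beta\rVert_1,$$

a convex maximum-entropy-style point-process objective, solved by
proximal-gradient (FISTA) iteration with backtracking to an objective
change below $10^{-8}$. Features are landscape layers standardized on the
background sample, plus their squares (unimodal responses); hinge and
threshold features are deliberately omitted to keep the optimizer small
and convex. The raw output normalizes to a probability distribution over
the background sample; the logistic output $cr/(1+cr)$ with $c = e^H$ (the
entropy of the fitted background distribution) puts a typical presence
near 0.5.

**Sampling bias.** Occurrence records are rarely collected evenly, so the
model would otherwise confuse collector effort with habitat. The package
builds a relative-effort surface as a quartic (biweight) kernel density of
points, rescaled to maximum 1 and floored at a small positive value, and
draws background cells with probability proportional to it: presences and
background then share the observation bias, which cancels from the
likelihood. On synthetic landscapes where the generating effort surface is
known, effort-weighted background sampling recovers the generating
coefficients with lower RMSE than uniform background in every replicate.
A real analysis only has the *estimated* kernel density of the points
themselves, which mixes true suitability into the effort estimate; the
correction is then weaker, and this is a genuine limitation of the
approach rather than of the implementation.

**Replication and thresholding.** An ensemble of runs (50 by default)
each trains on a random 75% of occurrences and tests on the remaining 25%
(253 records split 190/63), scoring test AUC by the tie-aware
Mann–Whitney estimator against the shared background sample. Each run
records its 10% minimum-training-presence threshold — the
$\lceil 0.1 n \rceil$-th smallest training presence score — and the
ensemble mean threshold binarizes the mean logistic surface (suitability
at or above the threshold counts as suitable).

**Variable importance.** MaxEnt's path-dependent "percent contribution"
bookkeeping is not reproducible from its description, so the package
reports two standard substitutes: jackknife training gains (each variable
alone, and the model without it) and permutation importance (drop in
training gain when a variable's values are permuted), normalized to sum
to 100%.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cell_size` | 500 | m | 25 ha cells; all area arithmetic follows from it |
| bias `bandwidth` | 2 × mean NN distance | m | scales the effort kernel to the point pattern; configurable |
| `floor_eps` | 1e-6 | – | keeps every cell sampleable as background |
| `background_n` | 10 000 | cells | standard presence-only background size |
| `reg_lambda` | $1/\sqrt{n_p}$ | – | shrinkage that vanishes with sample size; the original study's regularization is unstated |
| `train_fraction` | 0.75 | – | 75/25 train/test replication |
| `n_runs` | 50 | – | replicate uncertainty assessment |
| `mtp_percentile` | 10 | % | tolerant minimum-training-presence threshold |
| `nominal_density`, `nominal_occupancy` | 3, 0.03 | nests/ha, – | low-preference classes never surveyed |
| `bright_threshold` | 0.432 | MJ m⁻² h⁻¹ | 120 W m⁻², the WMO bright-sunshine definition |
| season | 89 days × 12 h | – | 1 Feb–30 Apr, non-leap; 12 candidate daylight hours |

Two conventions deserve emphasis because the published table is only
reproducible with them. Densities are rounded half-up to integers and
occupancies to two decimals *before* extrapolation (34 nests/ha from
39/114 plots, not 34.21), and each row product is floored before the
totals row is summed (146 275 × 0.23 = 33 643.25 → 33 643). The floored
convention is a reporting convention only: unfloored columns
(`*_raw`) are carried alongside and used for all raster arithmetic. A
guard of 10⁻⁹ inside the floor absorbs binary representation error in
decimal inputs such as 0.27.

The sunshine conversion from radiation to "hours" is a closed bound: an
hour with radiation exactly at the threshold counts. Night hours carry
radiation ≈ 0 and are excluded by the same rule, so no separate daylight
filter exists.

## The synthetic landscape

Real national layers (climate surfaces, a land-cover database, hourly
radiation grids) cannot ship with a package, so every stage is exercised
against a generator with known ground truth:

* **Environment** — smoothed-white-noise Gaussian random fields (separable
  truncated-Gaussian convolution; the smoothing length is the correlation
  length in cells). Elevation drives temperature through a 6.5 °C/km lapse
  rate, and degree days accumulate a per-cell sinusoidal annual cycle, so
  realistic inter-layer correlation exists.
* **Land cover** — per-class smoothed fields with offsets calibrated on the
  realized fields so class frequencies match requested weights while patch
  size follows the smoothing length.
* **Occurrences** — cells drawn ∝ exp(β_true · z) × effort, effort a
  quartic-kernel mixture, points jittered within cells.
* **Plot surveys** — occupancy Bernoulli(ψ_c); occupied plots hold
  1 + Poisson(λ_c − 1) nests, so counts concentrate on 0–3 as in the field
  data. The demonstration defaults mirror the original survey design:
  114/93/206/53 plots with ψ = 0.27/0.23/0.09/0 and λ chosen so expected
  densities are ≈34/29/9/0 nests/ha.
* **Sunshine** — per cell-hour Bernoulli bright indicators with a spatially
  smooth probability whose landscape mean is set so expected seasonal
  bright hours ≈ 540 h (the mean of the within-distribution reference
  stations in `reference_sunshine_hours()`); bright hours get radiation at
  or above the threshold, others zero.

What the generator does *not* emulate: anisotropy, coastlines and real
topography, temporal autocorrelation in weather, imperfect nest detection,
and spatial autocorrelation among survey plots. Passing tests therefore
demonstrate the pipeline's internal correctness and statistical behaviour
under its own assumptions, not performance on real New Zealand data.

## Numerical choices and degenerate inputs

* The likelihood uses log-sum-exp centering throughout; the L1 step is an
  exact soft-threshold, so `reg_lambda → ∞` collapses to the null model
  (all coefficients zero, logistic 0.5 everywhere) exactly.
* Zero-variance layers are dropped from the feature set with a logged
  warning rather than producing NaN standardizations.
* Nodata propagates: any cell flagged nodata in an input layer is nodata
  in every derived layer, and raster files store it as float32 NaN with
  the GDAL nodata tag.
* All-tied Kruskal–Wallis input returns H = 0, p = 1 rather than 0/0.
* Ties in AUC count one half (mid-rank estimator).
* Every generator and every pipeline stage consumes an explicit seed;
  stage-specific child seeds are derived from the one user seed, so a
  fixed configuration reproduces byte-identical tables.

Problem sizes in the shipped tests — 100 × 100 grids, 2 000 presences,
20 bias replicates, 2 000-replicate null calibrations — were chosen as the
smallest sizes at which the sampling tolerances stated in each test are
comfortably informative; the full suite runs in well under a minute.

## Raster I/O

No raster container or GeoTIFF codec suitable for float32 data is
available among this package's dependencies, so the package includes a
deliberately minimal one: single-band, uncompressed float32 GeoTIFF with
ModelPixelScale/ModelTiepoint georeferencing and GDAL-convention nodata,
plus a lightweight in-memory grid/layer pair (`si_grid`, `si_raster`)
with strict alignment checks. Write-then-read round-trips values (at
float32 precision), geometry and the nodata mask exactly, and the files
open in standard GIS tools; reprojection and multi-band imagery are out
of scope.

## Known limitations

* Detection in plot surveys is assumed perfect; reported densities are
  conservative and no occupancy-detection model is fitted.
* The "percent contribution" substitute is permutation importance; its
  numbers are not comparable to MaxEnt's path-dependent accounting.
* The bias correction can only be as good as the effort surface; the
  kernel density of the occurrences themselves confounds effort with
  suitability (see above).
* The totals-row "average density" of the published table is not
  derivable from its own printed values and is intentionally not emitted.
* Uncertainty is propagated only as the ensemble spread of AUC and
  thresholds; no bootstrap intervals on the extrapolated totals.
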