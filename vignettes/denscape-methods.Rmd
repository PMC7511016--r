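---
title: "Modelling alpine brown bear den selection and heli-ski disturbance risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling alpine brown bear den selection and heli-ski disturbance risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(denscape)
```

## The problem and the model

Brown bears hibernating in open alpine terrain excavate dens whose location
reflects a trade-off between terrain structure (diggable, stable, secure
slopes) and winter climate (deep, persistent, dry snow for insulation).
Helicopter-supported skiing operates in exactly this terrain in late
winter, when disturbance can trigger den abandonment. denscape models den
site selection, maps predicted denning habitat, and overlays helicopter
activity to rank disturbance risk.

Selection is modelled with an exponential resource selection function
(RSF),

$$w(x) = \exp(\beta_1 x_1 + \beta_2 x_2 + \dots + \beta_n x_n),$$

estimated by logistic regression of used (den) versus available (random)
locations. The design is second-order (den placement within the study
area) and Design II (dens pooled at the population level against a common
availability sample). Because availability is sampled at an arbitrary
density, the logistic intercept carries no biological information; `w` is
reported as a *relative* selection score and the intercept is dropped from
all surface predictions (`predict_surface()`). Wald standard errors give
95% confidence intervals ($\hat\beta \pm 1.96\,\mathrm{SE}$; the normal
quantile is used for determinism), and a coefficient is flagged
"informative" when its CI excludes zero.

The used:available imbalance is fit as-is, without case weights: with a
few hundred dens against thousands of available points this is the
standard naive-logistic RSF estimator, and only the intercept absorbs the
imbalance.

## Covariates

Eight covariates are derived from a digital terrain model (DTM) and
digital surface model (DSM), all on a shared 5-m grid:

| covariate   | definition                                     | units    |
|-------------|------------------------------------------------|----------|
| `dtm`       | elevation                                      | m        |
| `slope`     | Horn 3x3 finite-difference slope               | degrees  |
| `tpi`       | elevation minus mean elevation in a 140-m circular window (centre excluded) | m |
| `vrm`       | 1 − resultant length of unit surface normals in a 15-m window | 0–1 |
| `vhi`       | DSM − DTM (canopy height)                      | m        |
| `snow.load` | scaled elevation x leeward exposure            | 0–1      |
| `solrad`    | daily clear-sky insolation, 1 April            | Wh/m²/d  |
| `twi`       | ln(specific catchment area / tan slope)        | unitless |

Conventions worth spelling out, because each required fixing an open
choice:

* **TPI** excludes the centre cell from the window mean ("surrounding
  cells"); including it would only rescale the index, but one convention
  has to hold. Positive values are convex (ridges), negative concave.
* **Snow load** is the product of elevation scaled 0–1 over the study
  extent and a bearing-exposure term
  $W = (1 + \cos(\mathrm{aspect} - \mathrm{leeward}))/2$, maximal on the
  aspect opposite the prevailing storm wind (135° wind → 315° leeward) and
  zero windward. The cosine form is the simplest function that is
  standardized to [0, 1] and peaks exactly opposite the prevailing
  bearing. Flat cells, whose aspect is undefined, get $W = 0.5$ (no
  exposure information either way).
* **TWI** uses Freeman multiple-flow-direction (MD8, exponent 1.1) routing
  on a pit-filled copy of the DTM; $\tan\beta$ is floored at
  $\tan(0.1^\circ)$ so near-flat cells do not explode. A single-direction
  D8 option exists mainly to support independent cross-checks.
* **Solar radiation** is a clear-sky model: direct beam with fixed
  transmittance 0.7 per unit air mass plus isotropic diffuse (coefficient
  0.3), integrated over daylight in 15-minute midpoint steps, with
  self-shading only (no cast shadows). Only the *relative ordering* of
  cells enters the RSF, which the slope/aspect incidence term preserves;
  a full ray-traced model would change scores but barely the ranks.
* **Slope/aspect** follow Horn's method; grid-edge cells are nodata, and
  moving-window metrics elsewhere use the neighbours that exist — the
  study-area mask, not the raster border, decides validity.

All covariates are standardized, $(x - \bar x)/\mathrm{SD}(x)$, using the
mean and SD of the **availability sample**. Availability defines the scale
against which selection is measured; using the available points (rather
than used+available or all raster cells) keeps the standardization
independent of how many dens were found. The parameters are stored so the
transform inverts exactly.

## Study design

The study-area mask keeps cells within 1,500 m of the survey route
(expanded by half a cell diagonal so cells the route crosses are kept), at
or above 300 m elevation, non-forest (VHI ≤ 5 m) and non-glacier.
Available points are drawn uniformly over the continuous unmasked area at
500 points/km² by default. Raster cells are half-open (west/south edges
belong to the cell) so point-to-cell lookup is single-valued and the den
simulator's within-cell jitter inverts exactly.

Collinearity is screened (pairwise |r| < 0.7, VIF < 2) but violations are
*reported, not auto-dropped*: the candidate model set is fixed a priori,
and silently removing a covariate would change the hypotheses being
compared.

## The candidate set

Eighteen a priori models span terrain-only, terrain+vegetation, terrain
complexity, climate (dry-snow and thermal-insulation), combined, and
global hypotheses; quadratic terms always accompany their linear term.
Model 14 (elevation², slope², snow load, wetness, vegetation height,
ruggedness) is the reference structure that the den simulator uses as
truth. The candidate family is specified by hypothesis descriptions plus
parameter counts, and for three mid-ranked models the two cannot both be
honoured; where they disagreed, the parameter counts were treated as
definitive, and one model's stated count (12) is unreachable from its
factor list with powers ≤ 2 — it is encoded with the full 10-term
quadratic structure instead. These mid-table models
act only as competitors in ranking; the decisive structures (the terrain
models, model 13, 14, the no-ruggedness variants, and the global model)
are encoded exactly.

AICc uses $n$ = all rows (used + available). The small-sample correction
is negligible at these sizes, but the choice is recorded because
alternatives (e.g. $n$ = number of dens) change the correction term.
Ranking ties break by fewer parameters, then model id.

## Validation

`kfold_validate()` implements binned k-fold cross-validation: used points
are shuffled into 5 folds; each fold's model is refitted on the remaining
dens plus *all* available points (availability is shared across folds —
the expected-proportion construction needs every available point scored);
available scores are cut into 10 equal-count bins (upper-inclusive
breakpoints, ties to the lower bin); expected proportions are bin mean
scores normalized to sum 1; held-out dens are binned with the same
breakpoints to give observed proportions; and the fold statistic is the
Spearman rank correlation of observed versus expected. One "iteration" is
one random re-partition; the iteration statistic averages the five fold
correlations (pooling held-out points across folds before binning is
available via `pool_folds = TRUE`). Because the statistic is a rank
correlation, any strictly increasing transform of the scores leaves it
unchanged.

One practical caveat the package's own checks respect: for a *null* model
(dens placed with no selection), the cross-validated mean rho of a single
dataset does not converge to zero as iterations grow — re-partitions share
the same dens, and the dataset-level quirk persists (spread of roughly
±0.3 across landscapes, with a small negative bias from refitting noise).
The package therefore estimates the null expectation over replicate null
landscapes (six landscapes, ten iterations each, in the acceptance
checks), which is the quantity the ±0.35 sanity band is meant to bound.

## Habitat classes and risk overlay

`equal_area_classify()` sorts the raw cell values and places breakpoints
at the 20/40/60/80% pixel-count quantiles (equal numbers of pixels per
class, upper-inclusive intervals so each breakpoint is the upper limit of
its class). Prime denning habitat is the top two of five classes — by
construction 40% of the unmasked area, so any excess of dens above 40% in
those classes is selection, not bookkeeping. Massive ties that would make
an equal split impossible raise an error rather than a silent unequal
split.

Flight-track fixes become an intensity surface via a bivariate Gaussian
product-kernel density. The bandwidth minimizes the least-squares
cross-validation score
$\mathrm{LSCV}(h) = \int \hat f^2 - \tfrac{2}{n}\sum_i \hat f_{-i}(x_i)$
over a single multiplier on the per-axis standard deviations (coarse
log-spaced grid, then golden-section refinement); per-axis bandwidths are
a documented alternative but the default keeps one smoothing parameter.
Bandwidths are floored at one cell size, because duplicate-heavy fix data
drive LSCV towards $h = 0$. With more than 2,000 fixes the pairwise LSCV
score is computed on a random subsample of 2,000 (the density itself uses
every fix). Density evaluation is delegated to `MASS::kde2d`, with the
bandwidth passed as `4*h` to match that function's internal quartic
scaling convention.

The risk surface is the cellwise product of the *raw* intensity and *raw*
RSF surfaces (multiplying the 1–5 class grids is available as an option),
then classified into five quantile bins. Overlap summaries (prime-habitat
area inside permits, den counts in/out, dens per risk class, distance from
in-bounds dens to the permit boundary) are always computed from raw counts
first and rounded last.

## The synthetic landscape

The simulator generates everything the pipeline consumes, with defaults
chosen to emulate a coastal Alaskan alpine study system:

* **Terrain**: Fourier spectral synthesis (power-law filtered Gaussian
  noise, exponent 1.8) rescaled exactly to 300–2,048 m relief on a
  128x128 grid of 5-m cells. The exponent gives rugged but coherent
  alpine texture; larger exponents give smoother terrain (a tested
  property).
* **Canopy**: 15–30 m below a spatially noisy forest line (mean 480 m,
  sd 168 m), tapering through a krummholz transition to under 1 m in the
  alpine; DSM ≥ DTM everywhere.
* **Glaciers**: the top 15% of cells by elevation.
* **Route and heliports**: a smoothed polyline tracking the mid-elevation
  band, with three heliports at evenly spaced stations; flight fixes are a
  Gaussian mixture around heliports.
* **Dens**: exact importance sampling — cells drawn *without replacement*
  with probability proportional to $\exp(\beta x)$ on the standardized
  covariates, then jittered uniformly within the cell (corner + uniform
  offset, so the sampled cell is exactly recoverable). Sampling without
  replacement mirrors dens being distinct excavations and protects the
  fit from duplicate rows; the default landscape keeps the draw small
  relative to the eligible cells (~500 of ~10,000) so depletion does not
  visibly distort the selection function.
* The default truth is the model-14 structure with coefficients
  `(dtm, dtm², slope, slope², snow.load, twi, vhi, vrm) =
  (−1.91, −1.78, 0.64, −0.17, 0.23, −0.37, 0.18, −0.48)`.

Because a synthetic landscape of realistic cell size is far smaller than a
real 1,000-km² study area, the availability default of 500 points/km²
would yield only a couple of hundred points. The experiment helpers
therefore request the availability count explicitly (5,000 available
against 500 dens), preserving the availability-dominated regime of the
design at the reduced extent; the per-km² default remains the contract for
realistically sized masks.

What the simulator does *not* emulate: real IfSAR sensor noise and its
spatial error structure, weather-driven snow redistribution (the snow-load
index is a terrain proxy, and a physically based snow model is an explicit
non-goal), bear movement or multi-year den reuse, and land-cover classes.
Passing recovery tests therefore demonstrate that the estimation machinery
is correct and well calibrated under the assumed selection model — not
that the model is a complete description of real denning behaviour.

## Problem sizes and numerical choices

The replicated self-checks use 100 landscapes of 128x128 cells with 500
dens and 5,000 available points each; validation checks use 20
re-partitions for the true model and 6 replicate landscapes x 10
re-partitions for the null. Logistic fits use IRLS (`stats::glm`) with
tolerance 1e-10 capped at 100 iterations; a fit is rejected only when the
deviance collapses to zero (perfect separation) or the design is singular
(aliased terms are named in the error). Singular standardization (zero
variance) and degenerate classifications (ties spanning a quantile, zero
score variance) raise errors naming the offending quantity rather than
propagating NaN.

## Known limitations

* A single projected planar CRS in metres is assumed; there is no
  geographic-coordinate support and no raster I/O beyond plain matrices.
* The solar model is uncalibrated in absolute terms (fixed transmittance,
  no cast shadows); treat `solrad` as a relative covariate.
* The LSCV search assumes a unimodal score in the searched range; the
  coarse grid guards against local minima but pathological duplicate
  structures are only caught by the bandwidth floor.
* Spatial autocorrelation of dens (e.g. territoriality) is neither
  simulated nor corrected for; standard errors are conventional
  independence-based Wald errors, as in the naive RSF literature.
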