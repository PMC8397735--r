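---
title: "Emulating snapshot climate simulations over the late Pleistocene"
author: "paleoemu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating snapshot climate simulations over the late Pleistocene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoemu)
```

## The problem and the model

Equilibrium GCM snapshots exist for 72 dated epochs of the last glacial
cycle — 120 to 24 ka BP every 2 ka and 22 to 0 ka BP every 1 ka — but a
continuous transient simulation of the last 800 ka is computationally out
of reach.  `paleoemu` treats each coarse grid box independently and
learns, from those snapshots, how the local climate responds to the
external boundary conditions that distinguish one epoch from another:
obliquity, the two precession indices (e sin ω, e cos ω), atmospheric
CO₂, and the local surface type (ocean, land or land ice).  Applying long
forcing records to the fitted responses then yields a statistical
hindcast at arbitrary epochs.

Per pixel, month and variable the model is linear on a transformed
scale,

$$\Delta Y(x,t) = \beta_1(x)\,\Delta\varepsilon(t)
 + \beta_2(x)\,\Delta(e\sin\omega)(t)
 + \beta_3(x)\,\Delta(e\cos\omega)(t)
 + \beta_4(x)\,\Delta\mathrm{CO_2}(t)
 + \beta_5(x)\,M(x,t),$$

with $\Delta Y$ the anomaly of the transformed variable about its
training-epoch mean.  The assumptions are deliberate and worth stating:
snapshots are equilibrium states, so epochs are treated as independent
draws with no temporal autocorrelation; responses are linear in the
z-scored forcings; spatial coherence is not modelled but *emerges*
because neighboring pixels see the same forcings and have similar
coefficients (the package quantifies how well it is preserved via the
pixel-by-pixel spatial covariance matrix, `covarianceSummary()`); and the
product resolves millennial climatology only — no sub-millennial
variability exists in it by construction.

### Variable transforms

Temperature (K) enters untransformed.  Precipitation rate (mm yr⁻¹) is
log-transformed so the regression predicts anomalies in the exponent and
back-transformed values are strictly positive.  Cloud-cover fraction is
logit-transformed, confining predictions to (0, 1).  Pole rows are
excluded from fitting: bounded GCM variables reach exact zeros there and
the transforms are undefined; unfit pixels propagate as `NA`, never as
zeros.  Precipitation values below a configurable floor (default
0.1 mm yr⁻¹, `precipFloor` in `fitGrid()`) are clamped before the log
with a reported count — GCM output is never exactly zero away from the
poles, but other inputs can be.

### Surface type and the intercept

The surface type is treatment-coded with ocean as the reference level,
giving each level its own intercept shift ($\beta_5(\mathrm{ocean}) = 0$
by construction).  One design point deserves its own paragraph.  Centering
the response by its training mean and regressing on *uncentered* level
dummies without an intercept looks equivalent but is not: the constant
direction $\beta_5\,\overline{D}$ then lies outside the design span and
leaks into the forcing coefficients, so even noiseless data would not
return the generating $\beta$.  `fitPixel()` therefore includes an
intercept alongside the treatment-coded factor (reference = first level
observed at the pixel) and folds the fitted reference intercept into the
stored mean term.  Consequences that hold exactly: a prediction at the
forcing origin over the reference surface type returns the mean term; a
noiseless linear world is recovered to machine precision; levels never
observed at a pixel get no dummy column, and predicting such a level
substitutes the nearest fitted level (by code distance, ties toward the
smaller code) with a reported count.

### Training-set selection

The 80/20 split is not random.  Of the $\binom{72}{58}\approx 3\times
10^{14}$ possible splits, `selectTraining()` seeks those that keep the
forcing variance in the training set: it draws `nIterations` (default
10,000) uniform 58-subsets, marks as *candidates* those whose forcing
covariance eigenvalues — both spectra sorted descending — are elementwise
at least the full set's ("at least as much variance as the full data
set"; equality must pass, since the full set is trivially a candidate of
itself), counts each epoch's appearances in candidates, and takes the 58
top-ranked epochs.  Ties rank the older epoch first so the result is
deterministic given the seed.  The covariance uses the four continuous
forcings with the unbiased (n−1) denominator; the surface type is
categorical and has no place in it.  Selected epochs concentrate on the
edges of the forcing phase planes, so the fitted model interpolates for
the held-out epochs.  The split exists for validation only: the product
model is refit on all 72 snapshots.

### Forcing normalization

Forcings are z-scored with the mean and standard deviation of the
*fitting* epochs, and those statistics travel inside the
`EmulatorModel`: the coefficients are only meaningful under the
fitting-time scaling, so prediction reuses the stored statistics
verbatim (prediction-epoch forcing columns need not have mean zero).
CO₂ records arrive at irregular ice-core ages and are interpolated
piecewise-linearly to the 1 ka axis — the simplest scheme that is exact
at the raw sample ages; extrapolation outside the record is refused.

### Surface-type masks

`buildSurfaceMask()` classifies each cell at each epoch: preserved
inland lake cells keep their present-day class; remaining cells at or
below the epoch's sea level become ocean; remaining cells under the ice
extent become land ice (ice never converts sea-level ocean — such cells
are dropped with a warning); everything else is land.  Lowering sea
level therefore never shrinks the land+ice area when lakes are absent.
Epochs are integers in ka BP with present = 0, matching the 1 ka product
resolution.  Blending ice extents from heterogeneous sources is left to
the caller; the package accepts a single ice-extent history.

### Downscaling and bias correction

Coarse reconstructions are bilinearly interpolated (longitude periodic)
to the 0.5° output grid — 720 × 360 cells centered at −179.75…179.75°E,
−89.75…89.75°N — *before* correction.  Fine cells whose four coarse
neighbors include missing values take the nearest valid neighbor, with a
count; latitude is not periodic and out-of-span targets are an error.
The additive delta correction is implemented as

$$\hat Y(x,t) = Y_{\mathrm{ref}}(x,0) + \left[Y_{\mathrm{LM}}(x,t) -
Y_{\mathrm{LM}}(x,0)\right],$$

algebraically the standard delta method but arranged so the
reference-epoch identity is exact in floating point
($Y_{\mathrm{LM}}(x,0)-Y_{\mathrm{LM}}(x,0)$ is exactly zero), and
anomalies between any two epochs are preserved.  The delta is additive on
the natural scale for all three variables, with post-hoc clamping
(precipitation floored at 0, cloud to [0, 1]) and reported clamp counts;
clamping can be disabled to verify anomaly preservation.  Where the
reference is undefined (ocean, ice sheets, missing observational
coverage) the corrected product keeps the raw regridded emulation,
flagged in a provenance layer, so no fill values leak into statistics;
a `fillInvalid = "missing"` switch masks them instead.

### Bioclimatic variables

`computeBioclim()` derives BIO1 and BIO4–BIO19 (17 layers) plus minimum
annual temperature from monthly means.  Conventions, chosen once and
used consistently by code and tests: temperatures convert K → °C (the
extra minimum-temperature layer stays in K); BIO4 is the *population*
standard deviation of the 12 monthly means in °C, without the ×100
scaling some datasets apply; BIO5/BIO6 are the warmest/coldest
monthly-mean extremes so that BIO7 = BIO5 − BIO6 ≥ 0; quarters are the
12 sliding three-month windows with December–January wrap-around, ties
to the earliest window; monthly precipitation is a rate in mm yr⁻¹, so
BIO12 is the annual mean rate and month/quarter totals convert the rate
uniformly at 1/12 per month — a calendar-free convention; BIO15 is
100·sd/mean with a guard returning 0 for all-zero precipitation.  BIO2
(diurnal range) and BIO3 (isothermality) require monthly temperature
extremes that monthly means cannot supply and are never emitted.

## The synthetic world

`syntheticWorld()` generates complete inputs with the statistical
structure the analysis assumes, plus stored ground truth.  Defaults
describe late Pleistocene conditions: CO₂ a ~100 ka sawtooth in
[180, 300] ppm, obliquity a 41 ka cycle in [22, 24.5]°,
amplitude-modulated ~21 ka precession indices bounded by 0.06; the 72
snapshot epochs plus an 800…0 ka extension at 1 ka steps; a smooth
random topography with a sea-level history reaching −130 m at glacial
maxima and ice sheets grounding poleward of a glacial-state-dependent
latitude.  Transformed-scale noise defaults to sd 0.2 (temperature, K),
0.1 (log-precipitation) and 0.1 (logit-cloud).  The default grid is
12 × 10 — large enough for spatial structure, small enough that the full
suite runs in about a minute — with 96 × 73 used where full-scale
dimensions matter.

Two generator choices are deliberate.  First, the glacial index driving
sea level and ice extent is quantized to four discrete states, so the
set of surface types a pixel visits over the 72 snapshot epochs equals
the set it visits over the whole 800 ka extension; a pixel never shows
the emulator a level at prediction time that it withheld at training
time, which is what makes the noiseless end-to-end identity attainable
and is a reasonable idealization of stadial/interstadial state switching.
Second, truth fields are generated *in the fitted model's own family*
(linear response to z-scored forcings plus per-level intercepts), which
is exactly what makes recovery and coverage testable.  That is also the
generator's main limitation: passing tests demonstrate correctness of
the machinery, not that real climate is linear in its forcings — real
GCM responses include nonlinear and non-local dynamics (monsoons, storm
tracks) that a per-pixel linear emulator captures only partially, which
is why held-out RMSE maps for precipitation and cloud must be inspected
before trusting those fields regionally.

Synthetic proxies sample the local true annual temperature at irregular
ages with noise at a stated signal-to-noise ratio, optionally
affine-rescaled to mimic non-temperature archives; Pearson correlation
(the default in `proxyCorrelation()`, Spearman available) is invariant
to that rescaling.  Proxy samples pair with the nearest model epoch
within half the product resolution (0.5 ka by default, widened
automatically by `runPipeline()` for coarser epoch axes); unmatched
samples are dropped and counted.

## Numerical choices and degenerate inputs

- Symmetry of covariance inputs is enforced to 1e-10; eigenvalues come
  from the symmetric eigensolver, so the dominance check is exact for
  identical inputs.
- A constant response yields zero coefficients, R² = 0 by convention and
  RMSE = 0; rank-deficient designs (after level pruning) flag the pixel
  unfit with a reason rather than raising.
- The training-fraction count is `round(0.8 · n)` with ties rounding up
  (0.8 · 72 = 57.6 → 58).
- Coefficient significance uses per-coefficient two-sided t-tests at
  p < 0.05 without multiple-testing correction, matching how such
  coefficient maps are conventionally hatched.
- `NetCDF` files carry CF-style units and a ka BP time axis (positive
  into the past); longitudes are normalized to [−180, 180) on read with
  value columns permuted accordingly.  The reconstruction's default time
  axis includes epoch 0 (801 steps); an 800-step axis ending at 1 ka is a
  configuration choice.

## Problem sizes used by the tests

The suite exercises parameter recovery on a 12 × 10 world at noise sd
0.2 (1,248 pixel-month fits; median |β̂ − β|/SE ≈ 0.66, 95% CI coverage
≈ 0.95), the noiseless end-to-end identity over all 801 extension epochs
(max error ~2e-12 away from pole-influenced cells), bound preservation
over ~1.2e5 extreme-forcing predictions (zero violations), bioclim
agreement with an exhaustive-window oracle to 1e-10, and one full-scale
96 × 73 → 720 × 360 × 800 dimension run for a single variable.  These
sizes were chosen as the smallest that leave the statistical assertions
stable across seeds.

## Known limitations

Per-pixel linearity and forcing-interpolation assumptions as above; no
orographic downscaling or quantile mapping (the delta method preserves
anomalies but inherits the model's variance biases); no modelling of
temporal autocorrelation; marine-proxy comparisons conflate sea-surface
and air temperature at high latitudes where sea ice decouples them; and
the surface-type response is a pure intercept shift — a pixel that
changes class changes its level, not its forcing sensitivity.
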