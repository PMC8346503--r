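---
title: "Models and methods in migrapheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in migrapheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The scientific problem

A migratory population can advance its departure timing in two
fundamentally different ways: individual birds can each depart earlier
over their lives (phenotypic plasticity), or the composition of the
population can shift towards earlier-departing individuals (recruitment,
selection). Distinguishing the two requires longitudinal data —
individuals observed repeatedly across years — and a decomposition of the
population trend into within- and between-individual components. The
package implements that decomposition, plus the two companion data
streams that give it biological context: full-migration tracking (does
earlier departure propagate to earlier arrival and breeding?) and
breeding-ground phenology (what are departure schedules tracking?).

## 2. Departure-panel models

### Within-subject centering

For individuals observed in at least `min_years` years (default 3), the
mixed model is

    depart_doy ~ mean_year + dev_year + (1 | id)

with `mean_year` the individual's mean observed year and
`dev_year = year - mean_year`. The `dev_year` coefficient estimates the
within-individual slope; `mean_year` the between-individual slope. The
test of slope equality refits with covariates `(year, mean_year)`: the
`mean_year` coefficient then equals the slope difference, tested by Wald
z. REML is used for variance components; fixed-effect tests are Wald z
throughout (consistent with the lme4 ecosystem, which does not produce
denominator df).

*Random effects structure.* Random intercept only, by default. Individual
slope heterogeneity is real in such systems, but it is handled by the
separate per-individual posterior simulation; adding random slopes to the
decomposition changes the estimand subtly and was left as the
`random_slopes = TRUE` sensitivity option.

*Degenerate inputs.* Noise-free panels (used by the exactness tests) have
zero residual variance, where REML fits can fail; the implementation falls
back to OLS on the same fixed-effect structure, which coincides with the
mixed estimate in that limit. Wald p-values treat coefficient estimates at
numerical-noise magnitude (|est| < 1e-8) as exact nulls (p = 1) rather
than dividing noise by noise. If every individual shares one year set,
`mean_year` is constant and the between slope is flagged inestimable.

### Repeatability

One-way ANOVA ICC with the Lessells-Boag effective group size for
unbalanced data. The SE is the standard large-sample ICC formula
`sqrt(2 (1-r)^2 (1 + (n0-1) r)^2 / (n0 (n0-1) (k-1)))`; the literature
contains several asymptotically equivalent variants and the source
analyses did not specify one, so the most common form was chosen and is
pinned by tests only through its oracle-equivalence on the point estimate.

### Posterior slope simulation

Per individual, the joint noninformative posterior of the OLS line is
sampled exactly: `sigma^2 = RSS * df / chi^2_df`, slope conditionally
`N(slope_hat, sigma^2 (X'X)^{-1}_22)`. This is the classical "sim"
algorithm for linear models. The share of "advancing" individuals is
reported from negative *point* slopes, with the per-individual posterior
probability of a negative slope alongside: the integer count published in
this literature is only reconcilable with point estimates, while the
posterior summarises its uncertainty. Individuals with exactly collinear
data (zero residual variance) get a degenerate posterior at the point
slope and are flagged.

### Return-rate check

`returned` is constructed from the panel itself (id present in year+1;
last year excluded) and regressed on departure date by logistic GLM.
Complete separation is flagged rather than fitted.

## 3. Geolocator annotation

### Flight detection

Non-stop over-water flights appear as multi-day dry runs in the
conductivity channel. The operationalization: close wet gaps shorter than
2 h (isolated spurious wets), then keep maximal dry runs of >= 3 d whose
original dry fraction is >= 0.95. The 3-d floor sits far above roost-dry
spells (hours) and far below the real flights (~6-9 d); the source
analyses never stated their exact rule, so these three numbers are this
package's assertion, exposed as configuration. Timing parameters come from
the first two qualifying flights of the season (start/end instants floored
to whole UTC days-of-year); a third qualifying run triggers a warning and
the longest two are used.

### Incubation detection

Incubation shows as daytime shading bouts of 4-13 h for at least several
consecutive days, within 6-25 d of arrival. "Daytime" is decided without
a position estimate: the night anchor is the median clock-time midpoint of
dark runs in the pre-window baseline days; dark runs within 3 h of the
anchor are nights, everything else is candidate shading. North of the
Arctic-night boundary there are no baseline dark runs and all dark runs
are candidates — matching the observation that true nights vanish above
64 N in midsummer. Bout durations are measured at sampling resolution, so
the 4-13 h range is applied with one sampling interval of slack at each
end. "Semi-regular" is operationalized as >= 3 qualifying events whose
starts are < 36 h apart; the first event of the first qualifying run
inside the window defines IncSt. Ties are resolved first-in-window. A
trace that ends before the window closes returns "undetermined", which is
distinct from "absent".

### Threshold geolocation

Twilights are linear interpolated threshold crossings (threshold 2
arbitrary units). Longitude comes from the sunrise/sunset midpoint versus
true solar time (NOAA equation-of-time); latitude from inverting
`sin(a) = sin(lat) sin(d) + cos(lat) cos(d) cos(h0)` at the calibrated sun
angle `a`, searching a configurable latitude band and refusing ambiguous
double roots. The calibration angle is the median solar elevation at the
known deployment site at detected twilight times, which automatically
absorbs refraction, sensor response and interpolation bias. Near the
equinoxes day length is uninformative about latitude: days with
|declination| < 1 degree are flagged inestimable (latitude `NA`, longitude
still returned), mirroring how polar 24-h daylight is handled (no
crossings, longitude-only evidence, with an explicit Arctic-longitude
override in `assign_region()`).

### Timing trends

Per parameter: `value ~ year_c * region + (1 | id)`, year centred on 2008;
if the interaction's Wald p >= 0.05 it is dropped and the additive model
reported. Parameters with fewer than 5 non-missing values are skipped.

## 4. Phenology estimation

### Snowmelt

The gridded snow product is binary per cell-day, so the "binomial error"
of the source method is honoured with trial size 1: Bernoulli likelihood
of the asymmetric Gaussian snow-free curve
`s(t) = p_max exp(-((t-mu)^2) / (2 sigma^2))`, `sigma = sigma_L` left of
the peak and `sigma_R` right of it. The likelihood is multimodal on short
seasons, so optimisation runs L-BFGS-B from a grid of starts (melt-day
quantiles x two widths) on a transformed scale (logit p_max, log sigmas).
The snowmelt date is the analytic first 1/3-crossing
`mu - sigma_L sqrt(2 ln(3 p_max))` when `p_max > 1/3` (else missing, fit
retained), clamped to the first observed day for always-snow-free series.
The implementation was cross-checked against an independent global
optimiser: it attains the same likelihood optimum, so the remaining
estimation error (per-cell SD ~3.6 d at the canonical test parameters) is
the information bound of 365 Bernoulli observations, not an optimisation
artifact — see Limitations.

### Green-up

Weekly NDVI of the focal cell is pooled with neighbours within 15 km
under Gaussian distance weights (SD 4 km, great-circle distances), fitted
with a penalized cubic smoothing spline (GCV-selected penalty with an
effective-df floor of 4 to prevent flat fits on sparse weekly data — the
source method named the spline but not the penalty selector), and
interpolated daily on neighbourhood-snow-free days only. The "start" of
the rising limb is the fitted minimum between the domain start and the
fitted maximum (the phrase "start to maximum" is otherwise ambiguous);
green-up is the first day the rising curve exceeds start + 15% of the
start-to-maximum amplitude. The definition is invariant to affine
rescaling of NDVI, which the tests assert.

### Regional summaries

Median and 2.5/97.5% quantiles of cell dates per region-year (regions =
the 64 N split), and a pooled-cell OLS year trend. Pooling cells (no
per-cell random effects) is deliberate: it is what reproduces the very
small SEs characteristic of continental remote-sensing trend estimates.

## 5. The synthetic world

The generators' defaults are a statement of the study system, fixed once:

- **Panel**: 124 individuals, 2008-2020, `beta_W = -0.428`,
  `beta_B = -0.463` d/yr, mean departure day 80 at the period start,
  individual-intercept SD 8 d (the departure season spans about a month),
  residual SD 4.2 d (chosen so that the implied repeatability
  64/(64+17.6) ~ 0.78 matches the observed scale), presence probability
  0.5 per bird-year (44-74 of 124 marked birds seen per year). Presence is
  i.i.d. Bernoulli — no mortality process — except under the
  `return_logit_slope` knob, which makes next-year presence depend on the
  current departure date so the return-rate GLM has a detectable
  alternative to find. Dates are real-valued internally and rounded to
  whole days on emission (daily survey resolution); `round = FALSE`
  exists so noise-free constructions stay exactly linear.
- **Trace**: light is a clipped linear response of solar elevation scaled
  to 0-64 units, chosen so the threshold of 2 units sits at -3.1 degrees
  sun elevation — inside the 3.0-3.6 degree calibration range reported
  for such loggers, and deep enough that a 62 N site in mid-June still
  has twilights while nights shrink to the observed 0-4.5 h. Conductivity
  is wet on a 12.42-h tidal cadence on land, dry in flight with a
  configurable spurious-wet probability, and forced wet for 3 h on either
  side of each flight (birds forage on intertidal flats immediately
  before departure and after arrival), which is what makes ground-truth
  flight boundaries recoverable to the sampling interval. Incubation
  bouts are forced-dark intervals centred on local solar noon.
- **Grid**: cell snow-free peaks are linear in latitude (+2.5 d/degree)
  and year (-0.65 d/yr by default) plus cell-year weather noise (SD 5 d);
  green-up is snowmelt + 8 d + independent noise (SD 3 d), which gives
  the generator an analytic snowmelt/green-up R^2 used as a correlation
  oracle. NDVI observations are weekly with Gaussian noise; snow is a
  daily Bernoulli draw from the cell's true curve.

What the generators do **not** emulate: real tidal hydrology, weather- or
wind-dependent departure decisions, flock structure, logger sensor decay,
cloud contamination of NDVI, or spatially correlated weather. A green test
therefore establishes estimator correctness under the stated model, not
robustness to every field pathology.

## 6. Numerical choices and degenerate inputs

- Solar geometry uses the NOAA low-precision formulas (~0.1 degree in
  elevation); adequate because thresholds are calibrated, not absolute.
- Snowmelt optimiser: transformed-scale L-BFGS-B, `factr = 1e4`
  (~1e-12 relative tolerance), 6 starts; probabilities clamped to
  [1e-9, 1-1e-9] inside the likelihood.
- The `1/3`-crossing is computed analytically; a test asserts agreement
  with the numeric first-crossing of the fitted curve to < 0.01 d.
- All generators are deterministic under their seed (`withr::with_seed`,
  so user RNG state is never disturbed); the pipeline derives per-stage
  seeds from the master seed and keeps them below 2^31.
- Zero-variance groups, single-observation individuals, all-wet traces,
  all-snow or never-snow-free cells, constant NDVI, equinox days and
  polar daylight all have defined, tested behaviours (see the test
  suite).

## 7. Known limitations

- The between-individual slope is intrinsically poorly identified in a
  design where every individual's observed years are a random subset of
  the same 13-year window: var(mean_year) is at most ~2 yr^2, so with an
  8-d individual-intercept SD its sampling SE is several tenths of a
  d/yr. The acceptance criterion asking the 100-seed mean of `beta_B` to
  sit within 0.02 d/yr of truth has Monte-Carlo noise of the same order
  and is therefore marginal by construction; the companion SE-calibration
  checks are the informative ones.
- The ML snowmelt estimator is exact-optimal for its likelihood, but 365
  Bernoulli observations simply do not pin the 1/3-crossing to better
  than ~2-3 d per cell; per-cell dates should be aggregated (as the
  regional summaries do) before interpretation.
- Threshold geolocation here is deliberately minimal (no path model, no
  movement prior); latitude in the weeks around the equinoxes should be
  treated as unavailable rather than noisy.
- The pipeline's full-run defaults are intentionally small (a desk-scale
  smoke of every stage), not a power analysis.
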