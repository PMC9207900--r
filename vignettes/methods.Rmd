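---
title: "Emulating sectoral emission impacts on air quality and health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating sectoral emission impacts on air quality and health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqemu)
```

## The problem

Chemistry-transport models can tell us how ambient fine particulate matter
(PM2.5) and ozone (O3) respond to changes in anthropogenic emissions, but a
single annual simulation is expensive enough that only a few dozen runs are
feasible. `aqemu` implements the emulator-based strategy for getting around
this: a small, carefully designed set of simulations is used to train one
Gaussian-process (GP) regression model per grid cell per pollutant, and the
cheap emulators then stand in for the simulator across tens of thousands of
emission scenarios. On top of the emulators sit the downstream stages of a
national air-quality health assessment: observation-based concentration
scaling, chronic exposure metrics, attributable-mortality accounting by
sector, measurement-informed inference of emission changes, and scenario
search against air-quality targets.

The emulator input is an *emission configuration*: five scaling fractions
applied to 2015 baseline emissions of the residential (RES), industrial
(IND), land transport (TRA), agricultural (AGR), and power generation (ENE)
sectors, each within [0, 1.5]. The outputs are the two chronic exposure
metrics used by the health impact assessment: annual-mean PM2.5 (ug/m3) and
the maximum 6-monthly mean of daily maximum 8-hour O3 (6mDM8h, ppb).

## The synthetic world

Real applications of this design rest on proprietary-scale inputs: a
chemistry-transport model, a national emission inventory, thousands of
monitoring stations, gridded census population, and burden-of-disease
rate tables. The package replaces all of these with a first-class
synthetic world so the entire pipeline runs, and can be tested, from
nothing but a seed:

* **Domain** (`make_domain`): an `n_x` by `n_y` planar grid partitioned
  into contiguous-ish "prefecture" regions by Voronoi assignment to random
  seed cells, nested into "province" parents the same way. The default
  desk-scale world is a 10 x 10 grid with 8 prefectures in 3 provinces and
  25 monitoring stations; at this size every stage of the pipeline runs in
  minutes on one CPU while all structural properties (regional fallback,
  nearest-cell station pairing, per-cell emulation) are exercised.
* **Pseudo-simulator** (`simulate_concentrations`): a fixed, documented
  response surface standing in for the chemistry-transport model. PM2.5 is
  a per-cell baseline ("other sources") plus linear per-sector terms plus
  one interaction, `min(f_AGR, (f_IND + f_ENE)/2)`, mimicking
  ammonia-limited secondary inorganic aerosol formation. O3 has a
  VOC-driven industrial term and a linear-minus-quadratic land-transport
  term, giving a non-monotone NOx-titration-like response. This is the
  minimum structure that makes GP emulation non-trivial (smoothness, one
  interaction, one non-monotonicity); it has no meteorology, no transport
  between cells, and no chemistry beyond these forms, so passing tests
  demonstrate that the *pipeline machinery* is correct, not that any real
  atmosphere is well approximated.
* **Coefficient scales**: drawn per cell around means chosen so the
  baseline configuration produces a high-exposure regime (domain-mean
  PM2.5 near 50 ug/m3, sector shares of roughly 31% industry and 22%
  residential, O3 near 45 ppb). The high-exposure regime matters: it is
  what makes the attribution-vs-subtraction inequality a real test.
* **Demographics** (`make_demographics`): per-cell population anchored at
  2010/2015/2020 with linear interpolation between anchors (the standard
  treatment for census-year gridded products; the method between anchors
  is this package's choice). Twelve adult age groups (25-29 ... 80+)
  whose mass shifts older over time, and baseline mortality rates for
  NCD, LRI, and COPD rising steeply with age, with 95% intervals. Rates
  for 2020 are a linear continuation of each (outcome, age) series over
  2010-2019, floored at zero - again a documented package choice where
  only "extrapolated" is specified by the design.
* **True trajectory** (`true_trajectory`): a known year-by-year emission
  path for 2010-2020, pinned at baseline in 2015, with all post-2015
  values on the 0.2 configuration lattice. Because the generator's truth
  is known and on-grid, the measurement-informed inference can be tested
  as a parameter-recovery problem - something impossible with real
  observations.

## Experiment design

Training and test designs are maximin Latin hypercubes
(`latin_hypercube_maximin`): among `n_candidates` (default 200) random
Latin hypercube samples, the design maximizing the minimum pairwise
Euclidean distance wins. Defaults are 50 training and 5 test runs over
[0, 1.5]^5. The prediction grids are exhaustive lattices at 20%
increments: the full grid spans 0-140% (8 levels, 8^5 = 32,768
configurations) and the interior grid used by the emission inference
removes the 0% and 140% edges (6^5 = 7,776). The apparent tension between
a "0-150%" design space and 20% increments is resolved in favour of a top
lattice level of 140%, which is the only reading consistent with 8 levels
and with the interior grid's stated edges.

## The Gaussian-process emulator

Each (cell, pollutant) pair gets an independent zero-mean GP
(`gp_fit`) with:

* **Kernel**: Matern 5/2 with per-dimension length-scales (automatic
  relevance determination). The Matern 5/2 family is the standard default
  for smooth-but-not-analytic computer-experiment outputs; nothing in the
  source design pins a specific kernel, so this is a package decision.
* **Scaling**: inputs mapped to the unit cube by the design bounds;
  outputs centred and scaled to unit variance per cell, for conditioning.
* **Nugget**: a fixed jitter of 1e-6 on the standardized correlation
  diagonal. It absorbs simulator round-off and keeps Cholesky
  factorizations stable; predictions at training points are reproduced to
  well within the jitter's SD scale.
* **Hyperparameter fitting**: the process variance is concentrated out of
  the marginal likelihood analytically; the length-scales are optimized
  by L-BFGS-B on the concentrated negative log marginal likelihood from 6
  seeded starts (1 central + 5 random restarts), with ties broken by
  likelihood then lexicographically smaller log length-scales. Length
  scales are bounded in [0.05, 20] on the unit cube: the lower bound
  forbids pure-noise fits, the upper allows effectively linear
  dimensions. A constant training response short-circuits to a constant
  predictor.
* **Determinism**: each emulator's restart seed derives from the bank
  seed, the pollutant, and the cell index, so training is reproducible
  and independent of cell ordering.

Posterior predictive SDs are computed on request but deliberately *not*
propagated into the health results; the downstream accounting treats
emulator predictions as point estimates, and the reported 95% intervals
come from the health-side uncertainty sources only.

On the synthetic world the bank reproduces held-out simulations with
pooled test R^2 above 0.999 for both pollutants (the acceptance suite
requires at least 0.99), the desk-scale analogue of the fidelity such
emulators reach against real chemistry-transport output.

## Calibration to observations

The control (baseline) simulation is compared to station observations
with factor-style metrics: the normalized mean bias factor (NMBF) and
normalized mean absolute error factor (NMAEF). These are symmetric in
over/underestimation - a factor-of-two overestimate gives NMBF = +1, a
factor-of-two underestimate -1 - and only their values, not their
formulas, are fixed by convention upstream; the standard factor-metric
definitions are implemented and hand-checked in the tests.

Multiplicative scaling factors (`derive_scaling`) then match the control
run to observations per pollutant: ratio-of-means per prefecture where
the prefecture has stations, else the province's ratio, else the
domain-wide ratio. Ratio-of-means (rather than mean-of-ratios) is used
for robustness to near-zero station values. The same factors are applied
to the control field and composed onto all emulator predictions
(`apply_scaling`); training data are untouched, and the calibration is
time-invariant - one baseline-year scaling applied to all years.

## Exposure metrics

`six_month_dm8h` implements the chronic O3 metric on a fixed 365-day
no-leap calendar: 24 rolling 8-hour means per day (windows may run into
the next day; trailing windows truncated by the series end need at least
6 of 8 hours, the standard DM8h validity rule), daily maxima, then twelve
6-month means starting at each calendar month, with the windows that run
past December wrapping to the start of the same data year so that all
twelve windows have six months of data; the maximum of the twelve is
returned. Calendar-month anchoring and same-year wrapping are package
choices where only "12 separate 6-monthly means" is pinned upstream. The
implementation is checked against an exhaustive window-enumeration oracle
on seeded random years to 1e-9.

Exposures are population-weighted concentrations
(`population_weighted`), convex combinations of the in-scope cells.

## Health impact assessment

The PM2.5 burden uses the GEMM (Global Exposure Mortality Model)
exposure-response for non-accidental mortality (NCD+LRI):

RR(z) = exp( theta * ln(1 + z/alpha) / (1 + exp(-(z - mu)/nu)) ),
z = max(0, C - 2.4 ug/m3)

with the published shape constants alpha = 1.6, mu = 15.5, nu = 36.8
ug/m3 and age-specific theta values shipped as an overridable YAML
fixture (`inst/extdata/gemm_ncd_lri.yaml`) - they are external published
constants, not quantities this package estimates. The O3 burden uses a
log-linear COPD relative risk of 1.063 (95UI 1.029-1.098) per 10 ppb
above a 35.7 ppb counterfactual. Burdens are population attributable
fractions, PAF = (RR-1)/RR, applied to population x age fraction x
baseline rate, summed over cells and adult age groups.

Two sector accountings are provided and must not be conflated:

* **Attribution** (`attribute_sectors`): each cell's total burden is
  apportioned by zero-out concentration shares
  (C - C_without_sector)/C, clipped to [0, 1] and renormalized when the
  nonlinear overlap pushes the sum above one; the residual share is
  "other sources". Sector + other contributions are additive to the
  total by construction (tested to 1e-9 relative).
* **Subtraction** (`subtract_sector`): the burden difference between a
  configuration and the same configuration with one sector's emissions
  removed. Because the GEMM log-risk is concave at high exposure, the
  subtraction-method benefit of removing a sector is smaller than its
  attribution share wherever exposure is well above the inflection
  point; the test suite asserts this inequality on the high-exposure
  synthetic world, and the two methods converge (to ~1%) in a
  constructed low-exposure world with a zero counterfactual, where the
  attributable risk is linear through the origin.

95% uncertainty intervals (`burden_uncertainty`) combine the stated
sources - exposure-response coefficient (normal on theta or on the O3 RR
within its interval), baseline rates (triangular on lower/central/upper),
and age fractions (uniform multiplicative wiggle, renormalized to the
year's adult total) - by joint seeded Monte Carlo with 1,000 default
draws. Joint Monte Carlo rather than quadrature is a package decision:
it is exact under nonlinearity in the limit and the combination rule is
not pinned upstream. Degenerate (zero-width) inputs collapse the
interval to the point value.

`counterfactual_demographics` recomputes a burden with one year's
exposure and another year's demographics, isolating the contribution of
population aging and growth to burden trends.

## Measurement-informed emission inference

The inference inverts the emulators against observed concentration
trends by rejection matching (`match_configs`): for every interior-grid
configuration, the predicted change at each station's paired cell
(prediction minus baseline prediction) is compared with the station's
observed change from 2015 to each target year; predictions within
tolerance are retained, and a configuration's count increments once per
matching (station, year) pair. Counts are pooled across target years,
and by default only PM2.5 trends are matched (O3-only, both, and either
modes are exposed). The top 1,000 configurations by count - ties broken
by distance to baseline, then lexicographically - are summarized by
per-sector means and 5/25/50/75/95 percentiles (`informed_estimate`).

The "within 1%" criterion is implemented as a relative tolerance with an
absolute floor: a match requires |pred - obs| <= tol * max(|obs|, 1.0
concentration unit). A pure relative test retains nothing for
near-zero observed changes; the floor value of one concentration unit is
a package decision. Matching is per station (no requirement that one
configuration match all stations simultaneously), and the top-K cut
keeps exactly K rows after deterministic tie-breaking.

`recovery_experiment` validates the whole chain as a parameter-recovery
problem: observations are generated from a known on-grid configuration
with 5% multiplicative noise, and the top-1,000 per-sector mean must land
within one grid increment (0.2) of the truth. Across 20 seeded
replicates on the default study world the success rate is 100% (the
acceptance suite requires at least 90%). The estimate degrades
gracefully: wider top-K spread under larger noise, and an exact argmax
at the truth under zero noise.

## Scenario search

`scenario_search` exhaustively evaluates reductions of the free sectors
(default residential + industrial) on a lattice, holding the others
fixed, and returns all configurations whose national population-weighted
PM2.5 exposure meets the target, the Pareto-minimal reductions, and the
avoided mortality (subtraction method) relative to the reference
configuration. Infeasibility - e.g. a target below the non-sector
baseline concentrations - is returned as a result, not raised as an
error, since "these sectors cannot reach the target" is itself the
finding.

## Problem sizes, tolerances, and limitations

The shipped defaults are the desk-scale study conditions: a 10 x 10
domain (200 emulators), 50 + 5 simulator runs, 25 stations, 7,776-point
inference grid, 20-replicate recovery experiments, and 1,000-draw
uncertainty intervals. These sizes were chosen so the full test suite
and the acceptance script each complete in minutes on a single CPU while
every pipeline property remains exercised; all are function arguments
and scale up directly.

Numerical choices worth knowing: the GP nugget (1e-6) bounds achievable
interpolation accuracy; grid membership tests use exact lattice
arithmetic from `seq`, so user-supplied configurations should come from
the provided constructors; quantiles use R's default type-7 definition;
and the oracle comparisons in the tests run at 1e-8 (GP posterior mean)
and 1e-9 (6mDM8h) tolerances.

What passing tests do *not* show: realism of the pseudo-simulator
(no transport, chemistry, or meteorology), realism of the synthetic
demographic magnitudes (burden totals on the toy world are in the tens
of thousands, not millions), or the behaviour of the inference under
interannual meteorological variability, which the underlying design
explicitly excludes by fixing one meteorological year.
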