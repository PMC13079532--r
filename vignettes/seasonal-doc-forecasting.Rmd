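---
title: "Seasonal forecasting of riverine DOC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal forecasting of riverine DOC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docseer)
```

## The forecasting chain

`docseer` implements a complete seasonal forecasting chain for riverine
dissolved organic carbon (DOC) at the inlet of a drinking-water reservoir in
a Mediterranean, two-sub-catchment river system. DOC is the operational bulk
surrogate for dissolved organic matter, the precursor pool for disinfection
by-products, so anticipating above-normal DOC months gives water managers
lead time for upstream sampling, selective reservoir withdrawal and
treatment adjustments.

The chain has five stages, each a package module:

1. **Synthetic data** — pseudo-reanalysis "truth" weather and forecast
   ensembles with controllable skill and bias, so every downstream stage is
   testable without any external download.
2. **Catchment model** — a minimal daily rainfall–runoff and soil-carbon/DOC
   simulator with the I/O contract of a semi-distributed hydrology model
   feeding an in-soil carbon model (temperature and precipitation in;
   hydrologically effective rainfall HER, soil moisture deficit SMD,
   streamflow and DOC out).
3. **Calibration** — goodness-of-fit metrics (R², NSE, logNSE, KGE) at
   monthly aggregation and a ±25% Monte-Carlo parameter search with a
   carbon-pool stability screen.
4. **Bias correction and hindcasting** — empirical quantile mapping (EQM)
   with leave-one-year-out (LOO) cross-validation; hindcast execution with a
   5-year warm-up and model-state resets from the truth-forced reference
   run; verification with CRPS/CRPSS over 12 initialization months × 7 lead
   months.
5. **Forecast products** — tercile probabilities per lead month, a
   traffic-light skill classification, management action levels from the
   above-normal probability, and a machine-readable monthly report.

## The catchment simulator is a stand-in, by design

The simulator is **not** a re-implementation of any published catchment
model. Published coupled hydrology/in-soil-carbon chains encode their
process equations in their own codebases and documentation; this package
instead ships a deliberately small model with the same inputs and outputs
and the two properties the forecasting workflow actually exploits:

* runoff is mediated by HER and SMD from a soil bucket, so streamflow
  integrates weather over weeks (slow-reservoir residence time);
* DOC is produced from slow soil carbon pools, so DOC carries *system
  memory* over months to years.

Per land-cover unit (five classes: urban, agriculture, broad-leaved forest,
coniferous forest, small/no vegetation) and daily step:

**Hydrology.** Precipitation falls as snow when `T < T_snow`; melt is
degree-day limited, `min(snowpack, DDF·max(0, T − T_snow))`. Potential
evapotranspiration is `a_pet·max(0, T)`; actual ET is scaled by soil
wetness and capped at available water, `AET = min(PET·S/C_soil, S + W)`.
Saturation excess `HER = max(0, S + W − AET − C_soil)` splits into a quick
and a slow linear reservoir (fractions `β_q`, `1 − β_q`; release
`store/τ`). SMD is `C_soil − S`. The AET cap is what makes the water
balance close exactly; without it, clamping the soil store at zero would
silently destroy water.

**Carbon.** Three pools per unit (g C m⁻²): labile organic-layer carbon
`SOC_o`, mineral-layer carbon `SOC_m`, dissolved soil DOC `D`. Production
`k_p·SOC_o·Q10^((T−T_ref)/10)·(S/C_soil)` moves SOC_o → D; sorption
`k_sorb·D` moves D → SOC_m; mineralization `k_min·D` leaves the system;
export `D·min(1, HER/(S + 0.1 mm))` leaves with quickflow. SOC_o gains a
constant litter input. The update is explicit Euler with proportional flux
capping, so no pool can go negative. We also give the mineral layer a slow
mineralization loss (`k_min_m`, default 2×10⁻⁴ d⁻¹ ≈ 13-year turnover):
with sorption as its only flux the mineral pool would grow without bound,
no steady state would exist, and spin-up convergence and any pool-stability
screening would be meaningless. With the leak, total carbon obeys
`Δ(SOC_o + SOC_m + D) = Σlitter − Σmineralization − Σexport` exactly.

The pools represent the *labile, DOC-producing fraction* of soil organic
carbon, not total stocks — tens of g C m⁻², with an organic-layer turnover
of roughly 1.5 years under the default parameters. That choice puts DOC
concentrations in the 2–8 mg L⁻¹ range typical of such rivers and gives the
multi-year memory the workflow exploits, while keeping spin-up lengths
practical.

**Routing.** Reaches are processed upstream → downstream (C1 → C2). Local
runoff depth converts to discharge via `mm d⁻¹ · km² × 1000/86400 →
m³ s⁻¹`; DOC load is terrestrial export + a groundwater background
(`c_gw · slow flow`) + upstream load damped by an in-stream loss fraction +
point sources. C2 receives a continuous WWTP point source of 12 mg L⁻¹ at
0.13 m³ s⁻¹. Concentration is load/Q, flagged missing when Q = 0. There is
no routing lag between reaches: travel time in a system this size is below
the daily step.

The daily loop runs in compiled code (Rcpp); the exported single-step
functions `step_hydrology()`, `step_carbon()` and `route_network()` are the
readable reference, and the test suite asserts that composing them day by
day reproduces `run_simulation()` to 10⁻¹².

## The synthetic weather and forecast generator

`generate_truth_weather()` emulates what the chain needs from a reanalysis
product: a sinusoidal annual temperature cycle with AR(1) daily anomalies
(default persistence 0.75, innovation SD 1.6 °C), seasonally varying wet-day
occurrence with gamma intensities tuned to a Mediterranean bimodal regime
(autumn maximum, secondary spring peak, dry summer), and an elevation
offset making sub-catchment C1 4.5 °C colder (snow-affected) and 15%
wetter. Both sub-catchments share the same random draws — fully correlated
weather, which is the realistic limit for adjacent sub-catchments of one
catchment.

`generate_ensemble()` builds forecast members over the fixed 215-day
horizon (7 lead months; lead 1 is the initialization month itself, and in
the 365-day calendar all 7 lead months always fit inside 215 days). At lead
`l` the member anomaly is `λ(l)·truth anomaly + √(1−λ(l)²)·noise`, so the
member–truth correlation is dialled directly: λ = 1 reproduces truth, λ = 0
is climatological noise. Temperature works on additive anomalies about the
truth monthly climatology; precipitation is blended in a transformed
standard-normal space and mapped back through per-month mixed
Bernoulli–gamma quantiles, which preserves zeros, skewness and
non-negativity and is invertible (the λ = 1 limit reproduces truth to
numerical tolerance). Bias is additive for temperature and multiplicative
for precipitation.

What the generator does **not** emulate: spatially structured forecast
error, drift of bias with lead within a month, temporally correlated member
noise, and ENSO/NAO-like regime predictability. Passing tests therefore
demonstrate that the *chain* behaves correctly under controlled skill and
bias, not that any particular real forecast system has skill in any real
catchment.

The 365-day (`noleap365`) calendar is the default throughout the synthetic
chain: it makes the warm-up arithmetic exact (5 × 365 + 215 = 2040 daily
steps) and every lead month complete. Gregorian dates are supported for
user-supplied observational data.

## Calibration choices

All GOF metrics are assessed at monthly aggregation to match the seasonal
focus (daily also available). `logNSE` uses ε = 1% of the mean observation
to stay defined on dry days. KGE is the 2009 form (untransformed ratios).
DOC grab samples are compared as within-month sample means against monthly
means of the daily simulation — the observation operator is part of the
design, and it caps the attainable DOC NSE below 1 even for a perfect
model, which the tests assert rather than hide.

The Monte-Carlo search draws each named parameter multiplicatively in
[0.75, 1.25] (±25% of base), applied across all land-cover units. The
stability screen runs each candidate over its first forcing year repeated
five times and flags candidates whose pools still drift by more than 1%/yr
over the final repetition. Repeating one year is deliberate: under real
interannual weather the fast dissolved pool varies ~10% between years even
at statistical equilibrium, and a naive final-year state difference would
flag perfectly stable candidates. The objective is a configurable weighted
mean of monthly NSE(Q) and NSE(DOC) (default 50/50); the weighting is an
explicit design decision since standard practice varies.

## Bias correction

EQM is fitted per (initialization month, lead calendar month): pooled
member-days of that calendar month across training years versus pooled
pseudo-observation days of the same calendar month. 99 equally spaced
probabilities, type-7 empirical quantiles, linear interpolation between
matched quantiles, constant-shift tails. For precipitation a dry-day
threshold of 0.1 mm d⁻¹ with frequency adaptation prevents drizzle
inflation, and an all-dry observed month maps everything to zero.
Degenerate (constant) training samples fall back to a constant shift.

The LOO rule excludes the calendar year *containing the verified days* from
the observation training sample — for leads crossing the year boundary that
is the year after the initialization year. Excluding the initialization
year instead would leak the verifying January values of year y+1 into the
training sample for a November initialization of year y.

Both raw and corrected archives are first-class objects with a provenance
attribute: bias correction reduces marginal bias but can degrade
correlation-based skill, so a workflow must be able to run and compare
both.

## Verification

CRPS uses the standard empirical-CDF (NRG) estimator
`mean|xᵢ−y| − Σ|xᵢ−xⱼ|/(2m²)`, equal to the exact integral of
`(F(x) − 1{x≥y})²`; an independent piecewise-integration oracle is shipped
and the suite asserts agreement to 10⁻¹² on 1000 random ensembles. The fair
variant is available as an option. The climatological reference is the
observed monthly values of the target calendar month across the reference
years, excluding the verifying year (LOO — otherwise the reference is
rewarded with the verifying value itself; both modes are implemented). Each
grid cell is `1 − mean(CRPS_fc)/mean(CRPS_clim)` over years — the ratio of
mean scores (skill of the system), not the mean of per-year ratios. Cells
with fewer than 2 verification years or a degenerate climatology are
flagged missing, and negative values are never rounded away in stored
grids (rounding to zero is a display convention only).

Skill classes: high (CRPSS > 0.6), acceptable (0.6 ≥ CRPSS ≥ 0.2), none
(CRPSS < 0.2), boundaries inclusive on the acceptable side.

## Hindcasting and state memory

Every hindcast job concatenates a truth-derived warm-up (default 5 years;
1 year is insufficient to stabilize the carbon pools, and beyond 5 years
brings no further improvement for the default turnover times) with the
member's 215-day prediction window, and resets the model state from the
truth-forced reference run at the warm-up start. All members of one
initialization share identical warm-up forcing, hence identical warm-up
states; the engine computes that warm-up once and reuses it. Restart
equivalence is exact: resetting from a stored reference state and re-running
the same forcing reproduces the reference outputs bitwise, which the
acceptance suite asserts.

This state treatment is the mechanism behind the headline behaviour the
package reproduces: with forecast skill gone by lead 3 (λ → 0), DOC
hindcasts still beat precipitation hindcasts at leads 2–4, because the
carbon pools and slow flow stores carry initial-condition memory into the
prediction window while precipitation members are pure climatological
noise.

## Tercile products and the report

Tercile bounds are empirical 33.33%/66.67% percentiles per calendar month.
Climate variables default to the full hindcast reference window; streamflow
and DOC default to a later window, mirroring systems where an upstream
management change (e.g. WWTP installation) makes the early record
unrepresentative — mixing pre- and post-change conditions would bias the
"normal" category. Members exactly on a bound count as normal; most-probable
ties resolve toward normal, then toward the lower tercile. Action levels
from the above-normal DOC probability: watch (< 0.60), prepare
(0.60–0.70), act (0.70–0.80), escalate (≥ 0.80). The monthly report is
static and machine-readable (JSON plus a deterministic Markdown rendering),
shows 4 lead months, and never fabricates a skill class for a cell the
verification module flagged missing.

## Numerical choices and degenerate inputs

* Explicit Euler at the daily step with proportional flux capping — the
  simplest scheme consistent with daily forcing; positivity is guaranteed
  by construction and property-tested on random forcing.
* ε = 0.1 mm in the export fraction avoids division by zero in dry soil.
* Dry streams (Q = 0) flag concentration missing rather than dividing by
  zero; empty forcing returns an empty output with the state unchanged.
* Unit identities are fixed once: mm d⁻¹ over km² × 1000/86400 → m³ s⁻¹;
  mg L⁻¹ ≡ g m⁻³, so load (g s⁻¹) = conc × Q.
* All generators and searches are pure functions of (configuration, seed).

## Problem sizes used by the shipped tests

The test suite exercises the chain at desk scale: a 12-year synthetic truth
for module tests; 10-year archives for the bias-correction and balance
checks; and, for the stochastic skill-decay/memory experiment, 20 replicate
archives of 10 members × 10 years × 4 initialization months with the full
5-year warm-up (the compiled core makes this a couple of minutes). Full
operational scale (25 members × 24 years × 12 months = 7200 member-series
per variable and sub-catchment) is exercised structurally through job
enumeration and cardinality checks.

## Known limitations

* The catchment model is a minimal stand-in: no six-land-cover process
  fidelity, no in-stream temperature, sediments, nitrogen or reservoir
  processes, and its parameters are fixture values chosen for qualitative
  realism (summer low flow, autumn DOC flush), not calibrated to any real
  river.
* One forcing series per sub-catchment; no grids, regridding or spatial
  interpolation.
* Forecast-ensemble realism is limited to controllable correlation and
  marginal bias, as described above.
* Sparse DOC sampling means DOC calibration scores are structurally lower
  than streamflow scores — a property of the observation operator, not a
  defect of the search.
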