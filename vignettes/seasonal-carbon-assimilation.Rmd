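---
title: "Seasonal carbon-cycle data assimilation: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal carbon-cycle data assimilation: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonfuse)
```

## The problem

Tropical forests with a pronounced dry season show seasonal shifts in net
carbon exchange whose attribution — how much comes from gross primary
production (GPP), how much from the autotrophic (`R_a`) and heterotrophic
(`R_h`) components of ecosystem respiration (`R_eco`) — is hard to pin down
from any single measurement stream. `carbonfuse` addresses this by fusing
many irregular ecological time series with the mass-balance constraints of a
simple daily carbon box model, estimating separate wet- and dry-season
process parameters with uncertainty via Markov chain Monte Carlo.

## The forward model

Seven carbon pools are tracked (g C m⁻²): foliage `C_f`, wood `C_w`, fine
roots `C_fr`, coarse roots `C_cr`, litter `C_lit`, coarse woody debris
`C_cwd` and soil organic matter `C_som`. Each day:

* GPP is computed from leaf area index (`LAI = C_f / 61.035`; leaf mass per
  area 122.07 g m⁻², half assumed carbon) and the day's meteorology.
* A fraction `a_x` of GPP is allocated to each live pool
  (`a_f + a_w + a_fr + a_cr = 1`); a fixed fraction `rf_x` of each
  allocation is respired immediately (growth respiration, summing to
  `R_a`), the remainder grows the pool.
* Turnover moves foliage and fine roots into litter, wood and coarse roots
  into coarse woody debris; litter and CWD decomposition feed soil organic
  matter. SOM loses carbon only by respiration.
* Heterotrophic respiration from litter, CWD and SOM is a fraction `rf_p`
  of the pool, scaled by a Q10 temperature factor (`2^((T - 25.6)/10)`,
  doubling per 10 °C around the site mean temperature of 25.6 °C) and by
  the soil-moisture response described below.
* `NEE = R_eco - GPP` (negative = net uptake). Total carbon change equals
  `GPP - R_eco` exactly; the test suite asserts this to 10⁻⁶ g C m⁻² over
  multi-year runs.

Allocation, turnover and growth-respiration parameters of the four live
pools have independent wet-season and dry-season members, switched daily by
a season mask (dry when soil water content < 0.12 m³ m⁻³, the lower
quartile of the site SWC record). With 7 initial stocks, 8 + 8 + 8 seasonal
parameters, 2 decomposition rates and 3 heterotrophic respired fractions,
36 quantities are estimated.

A pool driven below zero marks the parameter draw as invalid (log-likelihood
−∞) rather than being clamped; clamping would silently break conservation.

### GPP submodels

Two formulations sit behind `gpp_config()`:

* `"standin"` (default): `GPP = g_max (1 − e^{−k·LAI}) · I/(I + I_half)`
  — a saturating light response with canopy capacity `g_max` = 16
  g C m⁻² d⁻¹, extinction `k` = 0.5 and half-saturation irradiance
  `I_half` = 8 MJ m⁻² d⁻¹. Defaults were chosen once so that a closed
  canopy (LAI ≈ 6.9) under 16 MJ m⁻² d⁻¹ yields GPP ≈ 10 g C m⁻² d⁻¹,
  the magnitude observed at strongly productive terra-firme sites, and so
  that the dry-season radiation increase raises GPP by several percent.
* `"acm"`: the aggregated canopy model, a big-leaf empirical formulation
  with ten coefficients plus leaf nitrogen, hydraulic terms and daylength.
  Its coefficients should be recalibrated against a detailed
  ecophysiological model per site; that calibration is out of scope here,
  which is why the self-contained stand-in is the default for tests and
  synthetic experiments. The stand-in omits soil-water-potential and
  hydraulic-resistance inputs entirely.

## The soil-moisture response

Heterotrophic respiration at seasonally dry sites declines with drying
soil. The response is derived from daily soil respiration (`R_s`) data:

1. subtract a constant root (autotrophic) component, 1.9 ± 0.3
   g C m⁻² d⁻¹ (half the two-year mean `R_s`; `"half-mean"` implements
   that estimator directly). Negative remainders are clamped at zero with a
   warning — dropping those days would shrink the sample, and a negative
   heterotrophic flux is not physical;
2. divide out the Q10 temperature factor;
3. fit `r_opt · exp(−0.5((ln w − ln w_opt)/s)²)` to the residuals against
   SWC by Levenberg–Marquardt — a curve log-normal in SWC, the natural
   unimodal positive form when the optimum and spread act multiplicatively
   (the location-scale-in-`ln w` reading of "log-normal"; the alternative
   reading in raw `w` is not implemented);
4. normalize so the optimum equals one (`normalize_response()`), making the
   curve a pure multiplier.

The synthetic generator carries its own truth (`w_opt` = 0.17 m³ m⁻³,
`s` = 0.4, optimum 2.5 g C m⁻² d⁻¹); the fitted curve's coefficients are
recovered to three figures from 577 days of synthetic chamber data, and to
< 0.02 m³ m⁻³ in `w_opt` from 200 noisy points (noise SD 0.1).

For assimilation the daily `R_s` series is thinned to one point per 30
calendar days to remove autocorrelation, taking every 30th day (the first
retained day falls 30 days into the series): 577 daily points yield 19.

## Observation operators and likelihood

Nine streams map onto the model: daily NEE (497 days, SE 2.66 g C m⁻² d⁻¹
as a constant per-day error); leaf (`R_f`), stem (`R_w`) and CWD (`R_cwd`)
respiration; soil respiration split into heterotrophic (`R_lit + R_som`)
and autotrophic (`R_fr + R_cr`, the constant 1.9 ± 0.3) components; LAI
(`C_f`/61.035); monthly litterfall (summed daily foliage turnover; the
per-day design SE is scaled by days in month); aboveground biomass
(`C_f + C_w`, SE 10% of value); and an annual dry:wet stem-growth ratio
(0.40 ± 0.09). The growth-ratio operator compares wood *growth inputs*
(allocation minus growth respiration) rather than net `ΔC_w`, so turnover
does not contaminate the seasonal accumulation signal.

Half-hourly eddy-covariance records pass three standard filters before
daily aggregation: night-time records with friction velocity u* < 0.15
m s⁻¹ are dropped; flux and storage values beyond 10 SDs of their series
are dropped; days with fewer than 40 surviving half-hours are discarded,
and remaining gaps are filled with the day's mean daytime (06:00–18:00) or
night-time value before summing.

Errors are treated as independent Gaussians: the data misfit is
`Σ((M − O)/E)²` summed over streams, the parameter prior adds
`Σ((ln p − ln p₀)/σ)²`, and the log-posterior is −0.5 times the total.
The prior spreads σ ∈ {0.25, 0.5, 0.75} per parameter are recovered from
the prior range descriptors, which equal `p₀·e^{∓σ}` to printed precision —
so the tabulated lower/upper values are one prior SD in log space, *not*
truncation limits. Accordingly proposals outside the range are **not**
rejected by default (`hard_bounds = FALSE`); several reference posterior
medians themselves lie outside the ranges, so hard truncation would
contradict the estimates the model is meant to reproduce.

### Steady-state pseudo-observations

Primary forest pools are near steady state on decadal scales, but the model
is not spun up to equilibrium (prohibitively expensive inside MCMC). At a
real site this is handled by seven pseudo-observations — the net change of
each pool over the run, observed as 0 with SE 2% of the initial stock
(`steady_state_pseudo_obs()`), included by default in `loglik_factory()`.

In a *twin experiment* these pseudo-observations are omitted
(`run_twin_experiment(steady_sd_fraction = NULL)`): the truth run that
generates the synthetic data is not itself steady (the truth vector is a
set of marginal posterior medians, not a jointly balanced draw), so
pool-change "observations" of zero would be data the truth never produced
and would bias recovery away from the truth. This is a property of twin
design, not of the site methodology.

## The sampler

Random-walk Metropolis–Hastings in log space: every proposal perturbs all
36 log-parameters independently by Normal(0, 0.004) and renormalizes the
seasonal allocation fractions to sum to one (mass balance requires
closure). Rejected steps repeat the current state. Chains start from the
prior medians. Site-scale configuration: 1.2 million steps, 200 000
burn-in, six chains, Gelman–Rubin potential scale reduction < 1.2 as the
convergence criterion, percentiles 50/15.9/84.1 as the summary (median ±1
SD for log-normal marginals), and 1000 randomly selected accepted runs
stored for flux accounting.

Joint (block) updates are used rather than single-parameter sweeps: the
small step SD with a healthy acceptance rate is consistent with joint
updates, and the choice is configurable in principle via a custom proposal.
Convergence is diagnosed after sampling, never used for early stopping.

### Desk-scale configuration

Tests and the acceptance script use `desk_chain_config()`: 50 000 steps,
10 000 burn-in, 3 chains, the same 0.004 step. On one CPU a full twin
experiment (8-year site, all streams at their reference counts) runs in
about 4–5 minutes. These chains are deliberately two orders of magnitude
shorter than the site-scale configuration, and they do **not** converge by
the Gelman–Rubin criterion (the site analysis needed 1.2 million steps with
this step size for exactly that reason). Consequences, verified in the
test suite and acceptance script:

* the acceptance rate still sits in a broad band around the site-scale
  40–45% (we assert 25–75%; the twin posterior is a little flatter than
  the real-site posterior, so acceptance runs somewhat higher, around
  65–70%);
* tightly constrained parameters that start near their posterior (e.g.
  growth-respiration fractions) are recovered; parameters whose posterior
  lies a long random-walk distance from the prior-median start may not yet
  cover the truth at 50 000 steps. The twin-recovery check therefore asks
  that the truth fall inside the 15.9–84.1 interval for at least 3 of the
  4 probe parameters (`a_f_wet`, `a_fr_dry`, `rf_f_wet`, `c_f0`).

## The synthetic site

`generate_drivers()` emulates a lowland tropical forest with a long
Aug–Nov dry season and a short March dip: SWC follows a smooth seasonal
plateau (soil moisture sits at its floor for months) plus AR(1) noise,
affinely rescaled to mean 0.17 and SD 0.04 m³ m⁻³, which places the lower
quartile at ≈ 0.12 (the dry-season threshold) and makes ≈ 25% of days
dry. Radiation (+3.5 MJ m⁻² d⁻¹) and temperature (+1.6 °C) are elevated
in the dry season — so GPP rises with dry-season light while `R_h` falls
with drying soil, the two mechanisms whose competition sets the seasonal
NEE signal. Precipitation is exponential with a seasonally suppressed mean
(≈ 3000 mm yr⁻¹). CO₂ trends upward ≈ 1.9 ppm yr⁻¹.

Observations are the operators applied to the truth run plus independent
Gaussian noise at the reference SEs. The NEE stream is additionally
rendered at half-hourly resolution (radiation-weighted diurnal split) with
injected low-u* night records, > 10 SD spikes and short days, purely to
exercise the aggregation filters. The generator does *not* emulate
instrument drift, flux-footprint effects, gap seasonality, the litterfall
pulse at dry-season onset, or sub-daily SWC dynamics — so passing twin
tests demonstrates internal consistency of model + sampler + operators,
not that the model captures those features of real data.

Truth parameters default to the reference posterior medians so twin
experiments probe the realistic parameter regime; truth observations at
zero noise reproduce the operators exactly (data misfit 0), and at default
noise the standardized residuals of the truth are standard normal
(Kolmogorov–Smirnov check in the suite).

## Numerical choices

* Daily mean temperature for the Q10 factor is `(t_min + t_max)/2`; the
  driver carries only min/max.
* The forward trajectory loop is compiled (Rcpp); a pure-R day-step is the
  readable reference and the two paths agree to 10⁻¹² in the tests.
  Likelihood evaluation precomputes all observation indices, so one
  posterior evaluation is one compiled forward run plus vectorized
  residuals (~1.5 ms for 8 years on one CPU).
* Curve fitting starts from the empirical maximum; the spread parameter is
  returned as an absolute value (the curve is even in `s`).
* Quantiles use the default empirical (type-7) definition.
* Monthly aggregation uses calendar months; annual sums divide by the
  number of simulated years with leap days included.
* Seasonal percent changes are reported under both conventions (relative
  to the wet value, and relative to the larger value), labelled, since both
  appear in site reporting.
* The annual net sink is reported relative to both GPP and `R_eco`,
  labelled by denominator.

## Known limitations

* The stand-in GPP model has no humidity, CO₂ or hydraulic response; ACM
  is provided but uncalibrated here.
* A hard parameter switch at the season boundary cannot represent gradual
  transitions, and a single dry/wet leaf-turnover pair cannot reproduce a
  litterfall pulse concentrated in the first weeks of the dry season.
* The moisture response is an empirical site curve; transferring it to
  other sites is not supported by anything in this package.
* Observation errors are independent Gaussians; within-stream error
  correlation and per-day NEE error models are not implemented.
* Desk-scale chains are diagnostic tools, not converged posteriors; any
  scientific use should run the site-scale configuration.
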