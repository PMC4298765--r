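# carbonfuse

Seasonal carbon-cycle data assimilation for a strongly seasonal tropical
forest: a seven-pool daily ecosystem carbon box model with separate wet- and
dry-season process parameters, a normalized log-normal soil-moisture
response for heterotrophic respiration, and a Metropolis–Hastings scheme
that fuses nine ecological observation streams into posterior estimates of
seasonal carbon fluxes, allocation and carbon use efficiency.

## Who this is for

Ecosystem modellers and carbon-cycle researchers who want to (i) attribute
seasonal changes in net ecosystem exchange (NEE) to gross primary
production (GPP) versus the autotrophic and heterotrophic components of
ecosystem respiration, (ii) estimate allocation and turnover parameters per
season with uncertainty, or (iii) study the behaviour of multi-stream
model–data fusion itself via fully self-contained twin experiments.

## The model and method

Seven pools (foliage, wood, fine roots, coarse roots, litter, coarse woody
debris, soil organic matter) are updated daily:

* `GPP = f(LAI, meteorology)` with `LAI = C_f / 61.035` (leaf mass per
  area 122.07 g m⁻², half carbon);
* allocation `A_x = a_x · GPP` with `Σ a_x = 1`; growth respiration
  `R_x = rf_x · A_x`; the remainder grows the pool;
* turnover routes foliage/fine roots to litter and wood/coarse roots to
  coarse woody debris; decomposition feeds soil organic matter;
* heterotrophic respiration `R_p = rf_p · C_p · 2^((T−25.6)/10) · f(SWC)`,
  where `f(SWC) = exp(−0.5((ln w − ln w_opt)/s)²)` is a log-normal
  soil-moisture response normalized to 1 at its optimum;
* `NEE = R_eco − GPP`; carbon is conserved exactly.

Allocation, turnover and growth-respiration parameters of the live pools
switch between wet- and dry-season values (dry: mean daily soil water
content < 0.12 m³ m⁻³, the lower quartile of the site record). The 36
parameters (7 initial stocks + seasonal pairs + decomposition and
heterotrophic fractions) carry log-normal priors and are sampled by
random-walk Metropolis–Hastings in log space (proposal SD 0.004; site
scale: 1.2 M steps × 6 chains, 200 k burn-in, Gelman–Rubin < 1.2;
desk scale for tests: 50 k × 3). The likelihood is Gaussian and
independent across streams: `−2 log L = Σ((M−O)/E)² + Σ((ln p−ln p₀)/σ)²`.

Because no site data ship with the package, a synthetic-data module
emulates the study conditions (8 years ≙ 2922 days, SWC 0.17 ± 0.04 m³ m⁻³
with an Aug–Nov dry plateau, dry-season radiation increase, and all nine
streams at their reference observation counts and standard errors),
so every stage — moisture-response fitting, eddy-covariance filtering,
assimilation, flux accounting — is exercised end to end.

## Worked example

```r
library(carbonfuse)

cfg   <- synthetic_config(seed = 1)       # 8-year synthetic site
truth <- truth_run(cfg)                   # forward run of the truth vector
obs   <- generate_observations(truth, cfg)

# soil-moisture response from daily chamber data
fit <- derive_moisture_response(obs$soil_daily, root_const = 1.9)
fit
#> moisture_response: w_opt = 0.1709 m3 m-3, s = 0.405, r_opt = 1.000 (normalized)

# daily NEE from half-hourly eddy-covariance records (u*, spike, gap filters)
nee <- aggregate_daily_nee(obs$halfhourly)
nrow(nee)
#> [1] 497

# desk-scale assimilation (about 4-5 minutes)
tw <- run_twin_experiment(seed = 1)
tw$ensemble
#> posterior_ensemble: 24000 pooled draws from 3 chain(s)
#>   acceptance: 68.1%, 67.7%, 68.2%
#>   max Gelman-Rubin: 3.06

subset(tw$flux_summary, quantity %in% c("nee", "gpp", "r_h", "cue"))
#>   quantity  kind wet_mean wet_sd dry_mean dry_sd   annual annual_sd
#> 1      nee  flux    0.544 0.1380    -1.83 0.2080  -14.413   39.0285
#> 2      gpp  flux    9.529 0.0348    10.28 0.0395 3547.928   13.1138
#> 3      r_h  flux    3.707 0.1456     2.07 0.0806 1207.528   47.3483
#> 4      cue ratio    0.332 0.0200     0.38 0.0207    0.344    0.0159
```

The desk-scale chains are deliberately two orders of magnitude shorter
than the site-scale configuration (1.2 M steps), so the Gelman–Rubin
statistic stays above the 1.2 convergence threshold — the summary is a
mixing diagnostic, not a converged posterior (see the methods vignette).
The assimilation still reproduces the qualitative seasonal attribution:
heterotrophic respiration drops ~44% into the dry season while GPP rises,
turning the forest from a weak wet-season source into a strong dry-season
sink with a higher dry-season carbon use efficiency.

The fitted moisture response recovers the generator's truth
(`w_opt` = 0.17 m³ m⁻³, spread 0.4); the NEE filters reproduce the 497
retained observation days; the flux summary reports wet/dry-season means
and annual sums (with SDs across stored posterior runs) for every flux,
stock and carbon use efficiency. `derived_metrics(site_flux_table())`
computes the same seasonal diagnostics from the shipped site reference
table — e.g. annual CUE 0.357, a 36.1% dry-season reduction in
heterotrophic respiration, and an annual sink of 341.4 g C m⁻² yr⁻¹
(9.1% of GPP).

The numbered scripts under `analysis/` run the same pipeline as a
narrative workflow (synthesize → fit moisture → assimilate → report),
writing tables under `results/`.

## Package layout

* `R/` — forward model (`run_forward`, compiled inner loop in `src/`),
  moisture response (`derive_moisture_response`), observation operators and
  filters (`predict_stream`, `aggregate_daily_nee`, `misfit`), sampler
  (`run_chains`, `gelman_rubin`, `posterior_summary`), synthetic site
  (`generate_drivers`, `generate_observations`), reporting
  (`seasonal_summary`, `derived_metrics`).
* `analysis/` — numbered workflow scripts.
* `vignettes/seasonal-carbon-assimilation.Rmd` — the model, its
  assumptions, parameter meanings, numerical choices and limitations.
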