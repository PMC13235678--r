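# ccoheat

Time-stratified case-crossover analysis of daily ambient temperature and
acute adverse events, with neighborhood-deprivation effect modification.

## The problem

Does an unusually hot (or cold) day change the odds of an acute adverse
event — the motivating application being fatal encounters with police —
and does that association differ between structurally deprived and
privileged neighborhoods? Cohort-style answers are confounded by
everything that differs between places and people. The case-crossover
design sidesteps this: each event serves as its own control, its event
day compared with the *other same-weekday days of the same calendar
month at the same location*. Every time-invariant confounder cancels;
weekday and seasonal patterns are matched away by construction.

`ccoheat` is aimed at environmental-epidemiology practitioners who have
(i) point events with dates, (ii) daily gridded weather (e.g. 4-km
daily temperature/precipitation products), and (iii) census-tract
population tables, and who want the full chain from raw tables to
stratified odds-ratio estimates.

## The model

For matched stratum *s* (one case day plus its 3–4 control days),
conditional logistic regression conditions on one event per stratum:

    ℓ(β) = Σ_s [ η_case,s − log Σ_{j∈s} exp(η_j) ],   η = Xβ

maximized by a purpose-built Newton–Raphson with analytic score and
observed information. Exposure (daily maximum temperature, `DT_max`)
enters linearly or as a natural cubic spline (2–4 df), the
parameterization chosen by AIC; holidays and a three-level
precipitation category are available as adjustment covariates. Odds
ratios are reported at the empirical percentiles of the case-day
exposure distribution against a referent temperature (OR ≡ 1 at the
referent; default 23.5 °C for `DT_max`, 17.1 °C for `DT_mean`), with
delta-method 95% intervals.

Neighborhood context uses the Index of Concentration at the Extremes,
ICE = (A − P)/T per tract for four dimensions (income, racialized
income, homeownership, education), cut into national terciles; the
model is refit per tercile and cross-tercile heterogeneity tested with
Cochran's Q at fixed temperature contrasts.

A seeded synthetic-data generator (weather grid, Bernoulli events with
known log-linear temperature effect, tract tables spanning the ICE
range) makes every stage testable without external data.

## Worked example

```r
library(ccoheat)

cfg <- synthetic_config(seed = 42L)        # known truth: beta = 0.006 / °C
weather <- generate_weather(cfg)
events  <- generate_events(cfg, weather)
linked  <- link_exposures(build_strata(events), weather)

sel <- select_parameterization(linked, lapply(
  list(model_spec(form = "linear", covariates = "holiday"),
       model_spec(form = "ns", df = 2, covariates = "holiday"),
       model_spec(form = "ns", df = 3, covariates = "holiday"),
       model_spec(form = "ns", df = 4, covariates = "holiday")), identity))
sel$table
#>   exposure   form df n_par    loglik      aic converged
#> 1    dtmax linear NA     2 -1257.532 2519.064      TRUE
#> 2    dtmax     ns  2     3 -1257.428 2520.855      TRUE
#> 3    dtmax     ns  3     4 -1256.927 2521.855      TRUE
#> 4    dtmax     ns  4     5 -1256.360 2522.720      TRUE

sel$best_fit
#> Conditional logistic fit: 856 strata, loglik -1257.5320, AIC 2519.0640
#>            coef      se       z exp(coef)
#> dtmax   0.00830 0.01133 0.73269   1.00833
#> holiday 0.47024 0.21355 2.20201   1.60038

or_at(sel$best_fit, c(2.5, 30))
#>   temp_c      log_or         se        or    ci_low  ci_high
#> 1    2.5 -0.17430115 0.23789086 0.8400439 0.5269934 1.339056
#> 2   30.0  0.05395036 0.07363289 1.0554322 0.9135930 1.219293
```

AIC picks the linear form (truth is linear), the fitted slope 0.0083 per
°C sits within one standard error of the generative 0.006, and a 2.5 °C
day carries about 0.84 times the odds of the 23.5 °C referent. One call
runs the whole chain — matching, linkage, AIC selection, percentile OR
table, exposure-response curve, ICE terciles with incidence rates,
stratified fits and Q tests — and writes every table as CSV:

```r
run <- run_pipeline(run_config(synthetic = cfg, outdir = "cco_out"))
```

A thin CLI wraps the same functions:
`inst/scripts/cco all --seed 42 --outdir cco_out`.

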