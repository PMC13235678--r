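---
title: "Methods: time-stratified case-crossover analysis of daily temperature"
author: "ccoheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-stratified case-crossover analysis of daily temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccoheat)
```

# The design

`ccoheat` studies whether daily ambient temperature shifts the odds of an
acute adverse event — the motivating application is fatal encounters with
police across the contiguous United States — using the **time-stratified
case-crossover design**. Each event day ("case day") is compared with the
*other days of its own calendar month that fall on the same day of the
week*, at the same location. Because every comparison is within one
person-place-month, all time-invariant confounders (neighborhood
composition, local policing intensity, demography) cancel by design, and
matching on weekday and month removes weekly and seasonal patterning. The
referent-day rule is symmetric and exhaustive ("time-stratified"), which
avoids the overlap bias of unidirectional referent schemes; a Gregorian
month contains four or five of any weekday, so every stratum has three or
four control days and no event is ever excluded.

Location is operationalized as the event's weather grid cell. The cell is
what gives case and control days a common exposure series, so matching on
anything finer (exact coordinates) would change nothing: exposure is
constant within a cell-day.

# Exposure and linkage

Exposure is the daily maximum temperature `DT_max` (°C) of the event's
grid cell, emulating 4-km daily gridded weather products; the daily mean
`DT_mean` is available as a sensitivity exposure. Events are assigned to
the cell whose centre minimizes the haversine great-circle distance, with
ties broken deterministically toward the smallest cell id. Each stratum
day is then linked, by cell and date, to:

* `dtmax_c`, `dtmean_c` — copied bit-exactly from the weather table;
* a precipitation category — 0 for a dry day, 1 for rainfall below the
  study-period mean (2.68 mm by default), 2 at or above it. A day
  exactly at the mean is assigned the wetter category so that category 1
  is strictly interior; the cut-off is a configuration constant, not
  recomputed per dataset, so stated results are reproducible;
* a holiday flag — by default the 11 US federal holidays with
  observed-date shifting (Saturday observed Friday, Sunday observed
  Monday; Juneteenth from 2021). The list is user-overridable by file
  because "major holidays" is a convention, not a fact of nature.

A stratum missing weather for *any* of its days is dropped whole, with a
warning: a matched set with incomplete exposure cannot contribute to the
conditional likelihood, and dropping single days would silently change
the referent structure.

# The conditional logistic model

Within stratum $s$ with day-level design rows $x_j$ and linear predictor
$\eta_j = x_j^\top\beta$, the probability that the case day is the
observed one, conditional on one event having occurred in the stratum, is

$$
P(\text{case} = i \mid s) \;=\;
\frac{e^{\eta_i}}{\sum_{j \in s} e^{\eta_j}},
\qquad
\ell(\beta) \;=\; \sum_s \Big[\eta_{\text{case},s}
  - \log \sum_{j\in s} e^{\eta_j}\Big].
$$

This conditions out any stratum-constant term — the stratum's baseline
odds, and with it every time-invariant covariate. The implementation is
a purpose-built Newton–Raphson on the exact conditional likelihood with
analytic gradient (score) and Hessian (observed information):

* start at $\beta = 0$; the conditional log-likelihood is concave, so a
  guarded full Newton step converges globally away from separation;
* step-halving (at most 30 halvings) whenever a step would decrease the
  likelihood;
* convergence when the likelihood improves by less than $10^{-10}$ or
  the gradient sup-norm falls below $10^{-8}$; at most 50 iterations;
* stratum-wise log-sum-exp uses a max shift for numerical stability;
* the coefficient covariance is the inverse observed information at the
  optimum, and $\mathrm{AIC} = -2\ell + 2p$.

Three degenerate situations are handled explicitly rather than left to
numerics. Columns constant within every stratum are non-identifiable
(the likelihood is exactly invariant to them) and are rejected with an
error naming the column. A stratum with no control days carries no
information and is excluded with a warning. Separation — a monotone
likelihood with no finite maximum — is declared when any coefficient
exceeds 50 in absolute value during iteration: an odds ratio of $e^{50}$
per unit is numerically meaningless, and the error names the offending
column.

## Exposure parameterization and AIC selection

Exposure enters either linearly or through a natural cubic spline with
2–4 degrees of freedom. The basis places boundary knots at the observed
exposure range and the $df-1$ interior knots at equally spaced quantiles;
the natural constraint (zero curvature at and beyond the boundaries)
gives linear extrapolation in the tails, where data are sparse. The
exposure is centred at the referent before basis construction — the
conditional likelihood is translation-invariant, so this affects
conditioning only, never estimates. `select_parameterization()` fits all
candidates on the same data and keeps the converged fit with minimal
AIC, breaking ties (within $10^{-8}$) toward fewer parameters and then
toward the linear form. Covariates are held fixed across candidates, so
the comparison isolates the exposure shape.

Holidays enter as one binary column; precipitation as two dummy columns
(categories 1 and 2 versus dry), matching the categorical adjustment
convention for rainfall.

# Reporting: odds ratios at percentiles

Results are anchored at a **referent temperature** — 23.5 °C for
`DT_max` (the conventional study-period median) and 17.1 °C for
`DT_mean` — where the odds ratio is 1 by construction. For any
temperature $t$, the contrast $c = b(t) - b(\text{ref})$ in the fitted
basis (zero-padded over covariate columns) gives

$$
\log\mathrm{OR}(t) = c^\top\hat\beta,\qquad
\mathrm{se} = \sqrt{c^\top\widehat\Sigma\, c},\qquad
\mathrm{CI}_{95} = \exp\!\big(\log\mathrm{OR} \pm 1.96\,\mathrm{se}\big),
$$

the delta method being exact for the linear form. ORs are reported at
the empirical 5th, 10th, 25th, 50th, 75th, 90th, 95th and 99th
percentiles of the case-day exposure distribution (type-7 quantiles,
i.e. linear interpolation of order statistics — one stated convention
rather than a dialect ambiguity). Percentiles are computed over *case
days*: the distribution the design actually samples. Whether all
stratum days or all grid-days would be preferable is genuinely open;
case days are the package's documented choice and the percentile base is
swappable.

# Neighborhood deprivation: ICE, terciles, heterogeneity

The **Index of Concentration at the Extremes** for tract $i$ is

$$\mathrm{ICE}_i = (A_i - P_i)/T_i \in [-1, 1],$$

with $A_i$ persons at the privileged extreme, $P_i$ at the deprived
extreme, and $T_i$ the measured population; four dimensions are carried
(overall income, racialized income, homeownership, education).
National terciles are cut at the 33.33% and 66.67% type-7 quantiles of
the *unweighted tract-level* distribution — tracts, not persons, are the
distribution's unit — with lower-closed boundaries (a tract exactly at a
cut-point falls in the more deprived tercile; deterministic, documented
tie handling). Tercile 1 is most deprived. Incidence rates per tercile
are pooled — $10^5 \times \sum \text{cases} / \sum \text{population}$ —
the standard incidence definition, stable to very small tracts, rather
than a mean of per-tract rates.

Effect modification is assessed by refitting the full model
independently within each tercile of each dimension (strata follow the
tract of their case), then testing the stratum-specific log-ORs at a
fixed contrast — the 99th and, separately, the 5th percentile against
the referent — with **Cochran's Q**:

$$
w_i = 1/\mathrm{se}_i^2,\quad
\bar\theta = \frac{\sum w_i \theta_i}{\sum w_i},\quad
Q = \sum w_i (\theta_i - \bar\theta)^2 \sim \chi^2_{k-1}
\text{ under homogeneity.}
$$

Stratified refits (no interaction terms) match the reporting convention
of stratified models; Q on a fixed contrast makes the test identical for
linear and spline fits.

# The synthetic-data generator

Every downstream stage is validated against seeded synthetic data with
known ground truth. The generator emulates the *structure* of the three
real sources, not their content:

* **Weather** — per cell, `DT_max` is a cell-specific mean (uniform
  10–20 °C across cells) plus an annual sinusoid of amplitude 12 °C
  peaking July 15 (northern-hemisphere convention) plus Gaussian noise
  (SD 3 °C); `DT_mean` is `DT_max` − 8 °C, a fixed monotone offset that
  is all the mean-temperature sensitivity path needs; precipitation is
  zero with probability 0.6, else exponential with mean chosen so the
  overall mean is 2.68 mm.
* **Events** — one Bernoulli draw per cell-day with
  $\mathrm{logit}\,p = \alpha_c + \beta_T(\mathrm{DT_{max}} - 23.5) +
  \gamma_H 1[\text{holiday}]$, defaults $\beta_T = 0.006$ per °C,
  $\gamma_H = 0.1$, $\alpha_c$ centred at $\mathrm{logit}(0.08)$ with SD
  0.3 across cells. A Bernoulli outcome (not Poisson) keeps each event
  day unambiguous for matching, mirroring the likelihood's
  one-case-per-stratum structure. The marginal rate 0.08 per cell-day is
  chosen for validation power — enough events per replicate for stable
  fits at desk-scale grids — not for epidemiological realism, where
  event rates are orders of magnitude lower.
* **Tracts** — populations uniform on 1 200–8 000; each dimension's
  extremes constructed from a polarization draw spanning −0.9…0.9 so
  the ICE distribution covers all three terciles by construction. Each
  cell carries a fixed tract assignment, mirroring the spatial join of
  events to tracts.

What the generator deliberately does **not** emulate: spatial
autocorrelation of weather between cells, real gridded-product topology,
realistic victim demographics, and reporting artefacts of real event
databases. Passing the validation suite therefore demonstrates that the
*estimator and pipeline* are correct under the stated generative model —
it does not certify robustness to the messiness of real data sources.

# Validation summary and problem sizes

The test suite checks, among others: exact calendar worked examples of
the referent scheme against a brute-force calendar scan; the conditional
likelihood against closed forms (uniform-null value $-\sum_s\log(m_s+1)$,
paired-logistic reduction, $\hat\beta=\log 2$ on the classic
$\{+1,+1,-1\}$ paired fixture) and against finite differences; the
Newton optimum against brute-force grid search and against an
established conditional-logistic implementation (agreement to
$10^{-6}$); the spline basis against an independent truncated-power
construction; and delta-method intervals against parametric simulation.

Calibration uses: 100 replicates of ~1 000 events each (18 cells × 2
years) for slope recovery and 95% CI coverage; 400 smaller replicates
(8 cells × 1 year) for type-I error of the Wald test under
$\beta_T = 0$; 200 replicates of three 150-stratum groups sharing one
slope for uniformity of Cochran's Q p-values; and 20 replicates for the
frequency with which AIC prefers the linear form under a linear truth.
These sizes give each check Monte-Carlo resolution well inside its
acceptance band while keeping the whole suite fast on one CPU.

# Known limitations

* Same-day exposure only: no distributed-lag structure, although heat
  effects can persist across days.
* Wald inference throughout; no exact conditional or permutation
  inference for sparse strata.
* The nearest-cell rule does not interpolate between cells, and the
  generator's cells are points, not polygons.
* ACS-style count uncertainty (margins of error) is not propagated into
  ICE values or tercile assignments.
* The AIC comparison holds covariates fixed; whether adjustment sets
  should co-vary with the exposure form is a modelling judgement left to
  the user.

# A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 42L)
run <- run_pipeline(run_config(synthetic = cfg, outdir = "cco_out"))
run$fit                 # selected conditional-logistic fit
run$or_table            # ORs at the percentile set
run$qtests              # Cochran's Q per dimension and contrast side
```
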