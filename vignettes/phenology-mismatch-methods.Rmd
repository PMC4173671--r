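---
title: "Methods: phenological mismatch, degree-day hatching and recruitment in a truncated population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenological mismatch, degree-day hatching and recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

## The scientific problem

In seasonal predator–prey systems, offspring survival depends on whether
the predator's reproductive timing lines up with the seasonal peak of its
prey. In the lake system this package models, perch larvae hatch in late
spring and must find zooplankton prey as soon as their yolk reserves are
exhausted; recruits then face competition and cannibalism from older
(age-3+) conspecifics. Two environmental forces act at once: lake warming
shifts and shortens the reproductive season, and a disease-driven
age–size truncation removed the large, old spawners, weakening
intraspecific density regulation. The package provides the full analysis
chain needed to ask how these interact: phenology estimation, a
degree-day egg-development model, a match/mismatch index, recruitment
regression with density-dependence interactions, and sliding-window
variability analysis — plus a synthetic-data generator so that every
stage can be validated against known truth.

## Phenology estimation

Spawning is observed as weekly trap counts. We model the spawning date
distribution as Gaussian in time and estimate its mean $\mu$ (peak day)
and standard deviation $\sigma$; the *duration* of the event is defined
as $4\sigma$, the span containing roughly 95% of spawning. A bin
recorded at day $d$ with width $w$ represents $[d - w/2,\, d + w/2)$.

The default criterion is a grouped multinomial likelihood: bin counts
$n_i$ are treated as multinomial with probabilities proportional to the
Gaussian mass $\Phi\!\big(\tfrac{d_i + w/2 - \mu}{\sigma}\big) -
\Phi\!\big(\tfrac{d_i - w/2 - \mu}{\sigma}\big)$. Using CDF differences
rather than midpoint densities matters because weekly bins are wide
relative to $\sigma \approx 5$–$7$ days; the likelihood is also exactly
invariant to rescaling all counts and behaves well at low totals. A
least-squares fit of $A\,e^{-(d-\mu)^2/2\sigma^2}$ (amplitude profiled
out) is retained as a cross-check and as the preferred criterion for
series that are repeated point samples rather than partitioned counts
(the zooplankton series). Optimisation is Nelder–Mead on
$(\mu, \log\sigma)$ from moment starting values, with a restart from the
optimum; years that fail (fewer than three non-empty bins, zero totals,
non-convergence, or a peak more than 60 days outside the observed
season) are flagged with a reason code, never interpolated.

## Degree-day hatching and the mismatch index

Egg development is modelled by heat summation: with daily temperatures
$T_d$, development threshold $T_0 = 4.9$°C and heat sum $H = 97$
degree-days (experimentally determined values for perch, constant over
the relevant temperature range), hatching occurs on the first day the
running sum of $\max(0, T_d - T_0)$ reaches $H$. Accumulation starts the
day **after** spawning and the result is whole days elapsed since the
spawn day, so constant 12°C gives $\lceil 97/7.1 \rceil = 14$ days —
the observed "about two weeks at spawning temperatures" anchor. At
constant temperature the closed form $\lceil H/(T - T_0)\rceil$ holds
exactly. If the heat sum is never reached an error is raised rather than
a sentinel returned. Temperature gaps up to 7 days are linearly
interpolated; longer gaps are an error.

Hatch phenology is propagated by quantiles: the hatch peak is the hatch
day of a spawner at $\mu$ (rounded to the nearest day before
accumulation), and the hatching duration LS is the span between hatch
days of spawners at $\mu \pm 2\sigma$ — the same 95% definition as the
spawning duration. Under constant temperature this is a uniform shift
(LS equals the spawning duration); when temperature rises through the
season, later spawners develop faster and LS is compressed. A
Monte-Carlo mode that simulates individual spawn dates exists purely to
validate the quantile propagation.

The match/mismatch index is
$$\mathrm{PM} = \text{zooplankton peak} - \text{hatch peak},$$
positive when larvae hatch before the prey peak. This sign convention
makes the fitted recruitment quadratic's optimum positive
($-\beta_2 / 2\beta_3^{\mathrm{low}} \approx +9.2$ days), i.e. highest
recruitment when hatching precedes the prey peak by about ten days,
consistent with larvae needing feedable prey sizes slightly after the
bloom begins. Which duration enters the recruitment model is ambiguous
in principle (spawning vs hatching period); both are computed and the
**hatching** duration is the default regressor, since it is the
biologically proximate quantity for first feeding.

## The recruitment model

One record per spawn year $y$: spawner count $S_y$, hatching duration
$\mathrm{LS}_y$, mismatch $\mathrm{PM}_y$, age-3+ abundance
$\mathrm{CA}_{y+1}$ and winter temperature $\mathrm{WT}_{y+1}$ during the
cohort's first year, and recruits $R_{y+2}$ counted at age 2. All
continuous predictors are centred in-sample *before* powers and
interactions are formed. Density regulation enters through a low/high
dummy $D$ split at the in-sample median of CA (low where
$\mathrm{CA} \le$ median), used instead of continuous interactions to
avoid over-fitting at $n \approx 40$. The selected structure is

$$\log R = \beta_0 + \beta_1^{D}\,\mathrm{LS} + \beta_2\,\mathrm{PM}
 + \beta_3^{D}\,\mathrm{PM}^2 + \beta_4\,S_c^2 + \beta_5\,\mathrm{CA}
 + \beta_6\,\mathrm{WT} + \varepsilon,$$

nine coefficient slots in total (intercept; LS and PM² each split by
level). Two structural choices deserve note. First, $\beta_4$ is
attached to the centred-then-squared spawner number $S_c^2$ — a single
quadratic term whose positive coefficient reproduces "recruitment
increases with spawner number above a threshold". Second, the selected
structure contains $S^2$ without an $S$ main effect. The backward
selector in this package enforces marginality (a main effect is not
dropped while its quadratic or interaction survives), so this preset is
provided declaratively via `preset_specs()` rather than being a
reachable end-point of `backward_select()`; we prefer the marginality
constraint for selection because it keeps centred-quadratic
interpretation stable, and keep the preset faithful to the selected
structure.

## Cross-validation, selection and diagnostics

`loo_cv_rmse()` implements leave-one-year-out CV literally: refit with
one year removed, predict it, repeat, report the root mean squared
prediction error (on the log scale for log responses). By default the
centring means **and** the CA median are recomputed inside every
training fold, a strict out-of-sample contract; a fixed-design mode
reuses the full-sample centres, in which case the result equals the
closed-form PRESS statistic $e_i/(1 - h_{ii})$ exactly (verified to
1e-10 in the tests — this identity is the implementation's oracle).
Without dummy splits the two modes coincide anyway, because OLS
predictions are invariant to affine reparameterisation.

Backward selection starts from the full candidate model and at each step
evaluates every admissible single deletion: a plain term may be dropped
(respecting marginality), and a dummy interaction may be *demoted* to
its main effect. The deletion with the lowest CV-RMSE is applied if it
does not exceed the current model's; otherwise selection stops. Ties are
broken toward higher-order terms, then alphabetically, for determinism.
An AICc cross-check (`aicc()`, Gaussian form
$n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting
coefficients plus the error variance) is provided via
`selection_aicc()`.

One behaviour of this procedure is worth stating plainly: like AIC,
leave-one-out CV retains a pure-noise term with non-vanishing
probability (roughly $P(\chi^2_1 > 2) \approx 0.16$ per term,
independent of sample size and noise level). Exact recovery of a sparse
true model from several inert candidates therefore happens in roughly
half of replicates, not nearly always; what the procedure does reliably
is retain the active terms and drop most inert ones. The tests assert
both the reliable properties and the exact-recovery rate, so this
characteristic is visible rather than hidden.

Residual diagnostics cover the three standard checks: lag-1
autocorrelation (Ljung–Box at lag 1), variance homogeneity (auxiliary
regression of squared residuals on fitted values, $nR^2$ against
$\chi^2_1$) and normality (Shapiro–Wilk), each with pass/fail at
$\alpha = 0.05$.

## Population variability

`sliding_cv()` computes the coefficient of variation (sample s.d. over
mean) of the yearly abundance series in every sliding window of 3–11
years, separately for the periods before and after the truncation year
(the split year belongs to the post period; windows advance by one
year). The standard error across overlapping windows ignores their
autocorrelation and is a descriptive error bar only — a documented
limitation, since overlapping windows share most of their years. CV is
exactly invariant to positive rescaling of the series, which the tests
assert.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, at the study's conditions:

* **Temperature**: cosine seasonal cycle (annual mean 9°C, amplitude
  6.5°C, peak day 210) plus a 0.03°C/yr warming trend and daily Gaussian
  noise (s.d. 0.5°C). Years have 365 days — leap days are omitted so the
  seasonal term's annual mean is identical across years and the warming
  trend appears exactly in yearly means.
* **Spawning**: Gaussian spawn dates binned weekly by CDF mass and
  allocated by one multinomial draw, so counts conserve the total
  exactly. In the full lake simulation the peak advances 0.35 d/yr from
  day 140 and $\sigma$ narrows from 7 toward 5 days — a two-week advance
  and one-week shortening of the duration over four decades.
* **Zooplankton**: Gaussian seasonal curve ($\sigma = 12$ d) advancing
  1 d/yr from day 179, with Poisson sampling noise, so the mismatch
  shrinks from three–four weeks in the early years to near zero in the
  last decade.
* **Recruitment**: drawn from the regression above with the fitted
  coefficient values as generative truth and log-scale error s.d. 0.3.
  Predictor sampling distributions for the recovery experiments — PM
  uniform on $[-5, 30]$ days, LS Normal(14, 3²) days, S lognormal(ln
  30000, 0.4²), CA lognormal(ln 20000, 0.5²), WT Normal(4, 1²)°C — span
  the historical mismatch regimes while keeping the design
  well-conditioned. They are stand-ins chosen for realism, not estimates
  of the real covariate distributions.
* **Abundance**: two-regime lognormal series (log-s.d. 0.3 pre / 0.6
  post, boundary 1976), the synthetic twin of the observed
  variability increase.

All generators take explicit seeds and restore the caller's RNG state.
What the generator does **not** emulate: age structure and its dynamics
(recruitment is statistical, not mechanistic), observation error in the
covariates, autocorrelated year effects, skewed or multimodal phenology,
and temperature-dependent egg mortality. Passing tests therefore
demonstrate that the pipeline recovers what it assumes — they do not
validate the biological model against real field data, which are not
publicly deposited.

## Problem sizes and numerical choices

The replicated recovery experiment uses 100 data sets of 300 years —
large enough that the Monte-Carlo standard error of each mean
coefficient is a few percent of its value, small enough to run in
seconds. Selection-consistency simulations use $n = 200$ with residual
s.d. 0.1; variability patterns use 60-year series over 20 seeds.
Convergence tolerance for phenology fits is `reltol = 1e-12` with a
simplex restart; fitted peaks are real-valued while observation days are
1-based integers. Ties in selection are resolved deterministically as
described above. Degenerate inputs (empty seasons, constant predictors,
non-positive responses under a log link, rank-deficient folds, heat sums
never reached) raise errors that name the offending year, field or
column rather than returning sentinels.
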