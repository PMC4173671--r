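# phenomatch

Analysis pipeline for predator–prey phenological match/mismatch in an
age–size-truncated fish population, modelled on a long-term lake
monitoring system (perch and their zooplankton prey).

## The problem and the models

Perch larvae must find zooplankton prey shortly after hatching, and then
survive competition and cannibalism from age-3+ conspecifics. Lake
warming shifts and shortens the reproductive season while demographic
truncation (a disease outbreak that removed large, old spawners) weakens
intraspecific density regulation. The package implements the full chain
needed to study how these forces interact:

1. **Phenology** — Gaussian curves fitted to weekly spawner catches and
   zooplankton counts; peak = fitted mean μ, duration = 4σ (the span of
   ~95% of the event). Default criterion: grouped multinomial likelihood
   over Gaussian bin masses (CDF differences per bin).
2. **Degree-day hatching** — eggs hatch when the cumulative daily excess
   over T₀ = 4.9 °C reaches H = 97 degree-days; at constant temperature
   T the development time is ⌈H/(T − T₀)⌉ days (14 days at 12 °C). The
   spawning curve is propagated quantile-wise (μ and μ ± 2σ) to a hatch
   peak and hatching duration LS.
3. **Mismatch index** — PM = zooplankton peak − hatch peak (days;
   positive when larvae hatch before the prey peak).
4. **Recruitment regression** — with all continuous predictors centred
   and D a low/high dummy split at the median number of age-3+ fish:

   log R = β₀ + β₁ᴰ·LS + β₂·PM + β₃ᴰ·PM² + β₄·S² + β₅·CA + β₆·WT + ε

   fitted by OLS, with leave-one-year-out cross-validation backward
   selection (marginality-respecting), an AICc cross-check, and residual
   diagnostics (lag-1 autocorrelation, homogeneity, normality).
5. **Variability** — coefficient of variation of yearly abundance in
   sliding windows of 3–11 years, before vs after the truncation year.

A synthetic-data module generates temperature, catch, zooplankton,
covariate and recruitment series with exactly this structure (the fitted
coefficients serve as generative truth), so every stage is testable
without the undeposited field data. See the methods vignette
(`vignettes/phenology-mismatch-methods.Rmd`) for assumptions, parameter
choices and limitations.

## Worked example

```r
library(phenomatch)

# weekly catches of 30,000 spawners, Gaussian spawn dates N(135, 7)
catches <- gen_spawner_catches(spawn_config(peak_doy = 135, sigma = 7,
                                            n_fish = 30000),
                               year = 1975, seed = 42)
fit_normal_phenology(catches)
#> Gaussian phenology fit (grouped-likelihood)
#>   peak day: 135.00
#>   sigma: 6.99 days
#>   duration (4 sigma): 27.95 days
#>   bins: 10 (total count 30000)

# propagate through the degree-day model with that year's temperatures
temps <- gen_temperature(temperature_config(years = 1975), seed = 42)
h <- hatch_phenology(fit_normal_phenology(catches), temps)
# -> hatch peak day 150, hatching duration 22 days (compressed from 28:
#    later spawners develop faster in a warming season)

zoop <- fit_normal_phenology(
  gen_zooplankton(peak = 165, sigma = 12, noise = "poisson",
                  year = 1975, seed = 42),
  method = "curve-least-squares")
mismatch_index(h, zoop)
#>   year  pm_days
#> 1 1975 15.29222     # larvae hatch ~15 days before the prey peak

# recruitment regression on 300 synthetic years recovers the truth
rec <- gen_year_records(300, truth_params(), seed = 1)
fit_model(rec, preset_specs()$recruitment)
#> OLS fit: n = 300, k = 9, R-squared = 0.975, sigma = 0.3015
#>         term   estimate        se         t          p
#>  (Intercept)  1.144e+01 2.652e-02 431.28036  0.000e+00
#>      LS:Dlow  8.108e-01 8.019e-03 101.10919 1.010e-228
#>     LS:Dhigh  1.140e-01 8.198e-03  13.89995  4.910e-34
#>           PM  6.087e-02 1.840e-03  33.08904 1.246e-100
#>    PM^2:Dlow -3.329e-03 2.622e-04 -12.69615  1.091e-29
#>   PM^2:Dhigh -3.740e-04 2.709e-04  -1.38060  1.685e-01
#>          S^2 -1.325e-12 2.451e-11  -0.05407  9.569e-01
#>           CA -3.143e-05 1.697e-06 -18.51635  4.062e-51
#>           WT -1.499e-01 1.710e-02  -8.76666  1.566e-16
```

The duration effect (LS) and the curvature of the mismatch response
(PM²) are strong at **low** competition/cannibalism and weak at high —
density regulation buffers the population against mismatch. The PM
quadratic's vertex, −β₂/(2β₃ˡᵒʷ) ≈ +9.2 days, is the
recruitment-maximizing mismatch: hatching about ten days before the
zooplankton peak.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on the
synthetic lake system, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # four decades of lake data -> results/data/
Rscript analysis/02_phenology.R     # yearly Gaussian fits -> results/phenology.csv
Rscript analysis/03_mismatch.R      # degree-day hatching + PM -> results/mismatch.csv
Rscript analysis/04_recruitment.R   # fits, CV selection, diagnostics
Rscript analysis/05_variability.R   # sliding-window CV pre/post truncation
```

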