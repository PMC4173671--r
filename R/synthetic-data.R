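# Generators for lake-system inputs with the statistical structure the
# downstream analysis assumes: seasonal temperature with a warming trend,
# Gaussian-in-time spawning and zooplankton curves, and log-recruitment from
# the centred quadratic/dummy-interaction regression.

#' Configuration for the daily water-temperature generator
#'
#' Describes a sinusoidal seasonal temperature cycle with a linear warming
#' trend across years and i.i.d. Gaussian daily noise.
#'
#' @param annual_mean Mean temperature (deg C) in the first simulated year.
#' @param amplitude Seasonal half-range (deg C); the seasonal term reaches
#'   `+amplitude` at `peak_doy`. Must be non-negative.
#' @param peak_doy Day of year at which the seasonal cycle peaks.
#' @param trend Linear warming trend (deg C per year).
#' @param noise_sd Standard deviation of daily Gaussian noise (deg C);
#'   non-negative.
#' @param years Integer vector of years to simulate (non-empty).
#' @return An object of class `temperature_config`.
#' @export
temperature_config <- function(annual_mean = 9, amplitude = 6.5,
                               peak_doy = 210, trend = 0.03, noise_sd = 0.5,
                               years = 1969:2008) {
  if (length(years) < 1L) stop("year range must be non-empty", call. = FALSE)
  if (amplitude < 0) stop("seasonal amplitude must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise s.d. must be >= 0", call. = FALSE)
  structure(list(annual_mean = annual_mean, amplitude = amplitude,
                 peak_doy = peak_doy, trend = trend, noise_sd = noise_sd,
                 years = as.integer(years)),
            class = "temperature_config")
}

#' Simulate daily water temperatures
#'
#' One value per day of year (1--365; leap days are not simulated so that
#' yearly seasonal-term means are identical across years) and per year:
#' annual mean plus linear trend since the first year, a cosine seasonal
#' term peaking at `peak_doy`, and Gaussian noise.
#'
#' @param cfg A [temperature_config()].
#' @param seed Integer seed; the generator draws no global random state.
#' @return A data frame with columns `year`, `doy`, `temp_c`.
#' @export
gen_temperature <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "temperature_config"))
  rng <- local_rng(seed)
  doy <- 1:365
  out <- lapply(cfg$years, function(y) {
    seasonal <- cfg$amplitude * cos(2 * pi * (doy - cfg$peak_doy) / 365)
    temp <- cfg$annual_mean + cfg$trend * (y - cfg$years[1L]) + seasonal +
      stats::rnorm(length(doy), 0, cfg$noise_sd)
    data.frame(year = y, doy = doy, temp_c = temp)
  })
  do.call(rbind, out)
}

#' Configuration for the weekly spawner-catch generator
#'
#' Spawning dates are Gaussian in time; fish are counted in weekly bins.
#' A bin recorded at day `d` represents the half-open interval
#' `[d - w/2, d + w/2)`, i.e. bins are labelled by their centre day.
#'
#' @param peak_doy Peak spawning day mu (day of year).
#' @param sigma Spread of the spawning distribution (days); must be > 0.
#' @param n_fish Total number of spawners caught; non-negative integer.
#' @param bin_width Width of the catch bins in days (>= 1); default weekly.
#' @param grid_anchor Day of year on which the bin-centre grid is anchored.
#' @return An object of class `spawn_config`.
#' @export
spawn_config <- function(peak_doy = 135, sigma = 7, n_fish = 30000,
                         bin_width = 7, grid_anchor = 4) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (n_fish < 0) stop("number of spawners must be >= 0", call. = FALSE)
  if (bin_width < 1) stop("bin width must be >= 1", call. = FALSE)
  structure(list(peak_doy = peak_doy, sigma = sigma,
                 n_fish = as.integer(n_fish), bin_width = bin_width,
                 grid_anchor = grid_anchor),
            class = "spawn_config")
}

#' Simulate weekly catches of spawning fish
#'
#' Assigns `n_fish` spawners to weekly bins by a single multinomial draw
#' with bin probabilities equal to the Gaussian mass falling in each bin
#' interval (CDF differences, not midpoint density). Counts sum exactly to
#' `n_fish`. Bins span the peak plus/minus five sigma.
#'
#' @param cfg A [spawn_config()].
#' @param year Year label attached to the series.
#' @param seed Integer seed.
#' @return A data frame with columns `year`, `doy` (bin centres), `count`.
#' @export
gen_spawner_catches <- function(cfg, year = 2000L, seed = 1L) {
  stopifnot(inherits(cfg, "spawn_config"))
  rng <- local_rng(seed)
  w <- cfg$bin_width
  lo <- cfg$peak_doy - 5 * max(cfg$sigma, w)
  hi <- cfg$peak_doy + 5 * max(cfg$sigma, w)
  k0 <- floor((lo - cfg$grid_anchor) / w)
  k1 <- ceiling((hi - cfg$grid_anchor) / w)
  centres <- cfg$grid_anchor + (k0:k1) * w
  mass <- stats::pnorm(centres + w / 2, cfg$peak_doy, cfg$sigma) -
    stats::pnorm(centres - w / 2, cfg$peak_doy, cfg$sigma)
  prob <- mass / sum(mass)
  counts <- if (cfg$n_fish > 0L) {
    as.integer(stats::rmultinom(1L, cfg$n_fish, prob))
  } else {
    integer(length(prob))
  }
  data.frame(year = as.integer(year), doy = centres, count = counts)
}

#' Simulate a zooplankton seasonal abundance series
#'
#' Counts follow a Gaussian-shaped seasonal curve
#' `amplitude * exp(-(d - peak)^2 / (2 sigma^2))` at the sampling days, with
#' optional Poisson or multiplicative lognormal sampling noise.
#'
#' @param peak Day of year of peak abundance.
#' @param sigma Temporal spread of the bloom (days); must be > 0.
#' @param amplitude Expected count at the peak.
#' @param noise One of `"none"`, `"poisson"`, `"lognormal"`.
#' @param noise_sd Log-scale s.d. for lognormal noise (ignored otherwise).
#' @param days Sampling days of year (default weekly).
#' @param year Year label.
#' @param seed Integer seed.
#' @return A data frame with columns `year`, `doy`, `count`.
#' @export
gen_zooplankton <- function(peak, sigma, amplitude = 500,
                            noise = c("none", "poisson", "lognormal"),
                            noise_sd = 0.2, days = seq(4, 365, by = 7),
                            year = 2000L, seed = 1L) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  noise <- match.arg(noise)
  rng <- local_rng(seed)
  mu <- amplitude * exp(-(days - peak)^2 / (2 * sigma^2))
  count <- switch(noise,
    none = mu,
    poisson = as.numeric(stats::rpois(length(mu), mu)),
    lognormal = mu * exp(stats::rnorm(length(mu), 0, noise_sd) -
                           noise_sd^2 / 2))
  data.frame(year = as.integer(year), doy = days, count = count)
}

#' Generative coefficients of the recruitment model
#'
#' Defaults are the fitted recruitment regression of the lake system:
#' log recruits at age 2 as a function of hatching-period duration (LS, by
#' competition/cannibalism level), the match/mismatch index (PM, with a
#' level-specific quadratic), centred squared spawner number, age-3+
#' abundance (CA) and winter temperature (WT), plus Gaussian noise on the
#' log scale.
#'
#' @param beta0 Intercept (log count).
#' @param beta1_low,beta1_high LS slope per day, at low/high CA.
#' @param beta2 PM slope per day.
#' @param beta3_low,beta3_high PM^2 coefficient per day^2, at low/high CA.
#' @param beta4 Coefficient of centred squared spawner number.
#' @param beta5 Coefficient of CA (per individual).
#' @param beta6 Coefficient of winter temperature (per deg C).
#' @param sigma_eps S.d. of the log-scale error term; non-negative.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(beta0 = 11.4828,
                         beta1_low = 0.8295, beta1_high = 0.1209,
                         beta2 = 0.0607,
                         beta3_low = -0.0033, beta3_high = -0.0009,
                         beta4 = 2.2e-11, beta5 = -2.9e-5, beta6 = -0.1637,
                         sigma_eps = 0.3) {
  vals <- c(beta0, beta1_low, beta1_high, beta2, beta3_low, beta3_high,
            beta4, beta5, beta6)
  if (any(!is.finite(vals))) stop("all coefficients must be finite",
                                  call. = FALSE)
  if (sigma_eps < 0) stop("error s.d. must be >= 0", call. = FALSE)
  structure(list(beta0 = beta0, beta1_low = beta1_low,
                 beta1_high = beta1_high, beta2 = beta2,
                 beta3_low = beta3_low, beta3_high = beta3_high,
                 beta4 = beta4, beta5 = beta5, beta6 = beta6,
                 sigma_eps = sigma_eps),
            class = "truth_params")
}

#' Sampling distributions for the recruitment-model predictors
#'
#' Defaults span the regimes observed in the lake system: mismatch PM from
#' strongly positive (larvae weeks before the prey peak) to slightly
#' negative, hatching duration LS around two weeks, and lognormal spawner
#' and age-3+ abundances.
#'
#' @param pm `c(min, max)` of the uniform PM distribution (days).
#' @param ls `c(mean, sd)` of the normal LS distribution (days).
#' @param s `c(meanlog, sdlog)` of the lognormal spawner number.
#' @param ca `c(meanlog, sdlog)` of the lognormal age-3+ number.
#' @param wt `c(mean, sd)` of the normal winter temperature (deg C).
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(pm = c(-5, 30), ls = c(14, 3),
                             s = c(log(30000), 0.4),
                             ca = c(log(20000), 0.5), wt = c(4, 1)) {
  structure(list(pm = pm, ls = ls, s = s, ca = ca, wt = wt),
            class = "predictor_config")
}

#' Draw yearly predictor records for the recruitment model
#'
#' @param n_years Number of spawn years to draw.
#' @param config A [predictor_config()].
#' @param start_year First year label.
#' @param seed Integer seed.
#' @return A data frame with columns `year`, `PM`, `LS`, `S`, `CA`, `WT`.
#' @export
gen_predictors <- function(n_years, config = predictor_config(),
                           start_year = 1L, seed = 1L) {
  stopifnot(inherits(config, "predictor_config"), n_years >= 1L)
  rng <- local_rng(seed)
  data.frame(
    year = seq.int(start_year, length.out = n_years),
    PM = stats::runif(n_years, config$pm[1], config$pm[2]),
    LS = stats::rnorm(n_years, config$ls[1], config$ls[2]),
    S  = stats::rlnorm(n_years, config$s[1], config$s[2]),
    CA = stats::rlnorm(n_years, config$ca[1], config$ca[2]),
    WT = stats::rnorm(n_years, config$wt[1], config$wt[2]))
}

#' Generate recruit counts from yearly predictors
#'
#' Computes the linear predictor of log recruitment with all continuous
#' predictors centred in-sample, the low/high competition dummy split at
#' the in-sample median of CA (low where CA <= median), the squared terms
#' formed after centring, and adds Gaussian log-scale noise:
#' `log R = b0 + b1^D LS + b2 PM + b3^D PM^2 + b4 S^2 + b5 CA + b6 WT + e`.
#'
#' @param records Data frame with columns `year`, `PM`, `LS`, `S`, `CA`,
#'   `WT` (no missing values).
#' @param truth A [truth_params()].
#' @param seed Integer seed.
#' @return Numeric vector of recruit counts, one per row of `records`.
#' @export
gen_recruitment <- function(records, truth = truth_params(), seed = 1L) {
  stopifnot(inherits(truth, "truth_params"))
  needed <- c("PM", "LS", "S", "CA", "WT")
  for (f in needed) {
    if (is.null(records[[f]])) {
      stop(sprintf("missing predictor field '%s'", f), call. = FALSE)
    }
    bad <- which(!is.finite(records[[f]]))
    if (length(bad)) {
      yr <- if (!is.null(records$year)) records$year[bad[1L]] else bad[1L]
      stop(sprintf("missing value for predictor '%s' in year %s", f, yr),
           call. = FALSE)
    }
  }
  rng <- local_rng(seed)
  pm <- records$PM - mean(records$PM)
  ls <- records$LS - mean(records$LS)
  s  <- records$S - mean(records$S)
  ca <- records$CA - mean(records$CA)
  wt <- records$WT - mean(records$WT)
  low <- records$CA <= stats::median(records$CA)
  b1 <- ifelse(low, truth$beta1_low, truth$beta1_high)
  b3 <- ifelse(low, truth$beta3_low, truth$beta3_high)
  eta <- truth$beta0 + b1 * ls + truth$beta2 * pm + b3 * pm^2 +
    truth$beta4 * s^2 + truth$beta5 * ca + truth$beta6 * wt
  eps <- stats::rnorm(nrow(records), 0, truth$sigma_eps)
  exp(eta + eps)
}

#' Draw a complete set of yearly records including recruits
#'
#' Convenience wrapper: draws predictors from `config`, then recruit counts
#' from `truth`. The recruit column is named `R`.
#'
#' @inheritParams gen_predictors
#' @inheritParams gen_recruitment
#' @return A data frame with columns `year`, `PM`, `LS`, `S`, `CA`, `WT`,
#'   `R`.
#' @export
gen_year_records <- function(n_years, truth = truth_params(),
                             config = predictor_config(), start_year = 1L,
                             seed = 1L) {
  rec <- gen_predictors(n_years, config, start_year, seed = seed)
  rec$R <- gen_recruitment(rec, truth, seed = seed + 500000L)
  rec
}

#' Two-regime abundance generator configuration
#'
#' Yearly lognormal abundances with a change in log-scale dispersion at a
#' boundary year, emulating a population whose variability increases after
#' demographic truncation. The per-period `mean` parameters are the medians
#' of the lognormal draws (so zero dispersion yields exactly that value).
#'
#' @param split_year First year of the post-truncation period.
#' @param mean_pre,mean_post Median abundance in each period (> 0).
#' @param sdlog_pre,sdlog_post Log-scale s.d. in each period (>= 0).
#' @return An object of class `abundance_regime`.
#' @export
abundance_regime <- function(split_year = 1976, mean_pre = 5000,
                             mean_post = 5000, sdlog_pre = 0.3,
                             sdlog_post = 0.6) {
  if (sdlog_pre < 0 || sdlog_post < 0) {
    stop("log-scale s.d. must be >= 0", call. = FALSE)
  }
  if (mean_pre <= 0 || mean_post <= 0) {
    stop("period mean abundance must be > 0", call. = FALSE)
  }
  structure(list(split_year = split_year, mean_pre = mean_pre,
                 mean_post = mean_post, sdlog_pre = sdlog_pre,
                 sdlog_post = sdlog_post),
            class = "abundance_regime")
}

#' Simulate a yearly abundance series with a dispersion regime shift
#'
#' @param regime An [abundance_regime()]; its boundary year must lie inside
#'   the simulated range.
#' @param n_years Number of years (>= 2).
#' @param start_year First simulated year.
#' @param seed Integer seed.
#' @return A data frame with columns `year`, `abundance` (all > 0).
#' @export
gen_abundance <- function(regime, n_years, start_year = 1946L, seed = 1L) {
  stopifnot(inherits(regime, "abundance_regime"))
  if (n_years < 2L) stop("need at least 2 years", call. = FALSE)
  years <- seq.int(start_year, length.out = n_years)
  if (regime$split_year <= years[1L] || regime$split_year > years[n_years]) {
    stop("regime boundary year must fall inside the simulated range",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  post <- years >= regime$split_year
  med <- ifelse(post, regime$mean_post, regime$mean_pre)
  sdl <- ifelse(post, regime$sdlog_post, regime$sdlog_pre)
  data.frame(year = years,
             abundance = med * exp(stats::rnorm(n_years, 0, sdl)))
}
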