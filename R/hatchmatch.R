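# Propagation of the spawning distribution through a degree-day
# egg-development model to larval-hatching phenology, and the signed
# predator-prey match/mismatch index.

#' Degree-day egg-development parameters
#'
#' Eggs hatch once the cumulative daily temperature excess above a
#' developmental threshold reaches a fixed heat sum. Defaults are the
#' experimentally determined values for perch eggs: 97 degree-days above
#' 4.9 deg C, constant over the temperature range the larvae experience.
#'
#' @param heat_sum Required heat sum H in degree-days (> 0).
#' @param threshold Developmental threshold temperature T0 (deg C).
#' @return An object of class `degree_day_params`.
#' @export
degree_day_params <- function(heat_sum = 97, threshold = 4.9) {
  if (heat_sum <= 0) stop("heat sum must be > 0", call. = FALSE)
  structure(list(heat_sum = heat_sum, threshold = threshold),
            class = "degree_day_params")
}

# Regularise a one-year temperature series to a daily grid, linearly
# interpolating gaps of up to `max_gap` days; longer gaps are an error.
daily_temperatures <- function(temps, max_gap = 7) {
  s <- as_daily_series(temps, "temp_c")
  gaps <- diff(s$doy)
  if (any(gaps > max_gap + 1)) {
    stop(sprintf("temperature gap of %d days exceeds %d-day interpolation limit",
                 max(gaps) - 1L, max_gap), call. = FALSE)
  }
  grid <- seq(min(s$doy), max(s$doy))
  data.frame(doy = grid,
             temp_c = stats::approx(s$doy, s$value, xout = grid)$y)
}

#' Days from spawning to larval hatching under a degree-day model
#'
#' Accumulates `max(0, T_d - T0)` over the days following spawning;
#' hatching occurs on the first day the running sum reaches the heat sum.
#' Accumulation starts the day after spawning, and the return value is the
#' number of whole days elapsed since the spawn day (so a constant 12 deg C
#' gives `ceiling(97 / 7.1) = 14` days). Gaps in the temperature record of
#' up to 7 days are filled by linear interpolation; longer gaps are an
#' error.
#'
#' @param temps Data frame with columns `doy`, `temp_c` covering the spawn
#'   day through the candidate hatch window.
#' @param spawn_doy Spawning day of year (integer; fractional values are
#'   rounded to the nearest day).
#' @param params A [degree_day_params()].
#' @return Integer number of days until hatch.
#' @section Errors: If the heat sum is never reached within the series an
#'   error of class `phenomatch_no_hatch` is signalled; there is no
#'   sentinel return value.
#' @export
days_to_hatch <- function(temps, spawn_doy, params = degree_day_params()) {
  stopifnot(inherits(params, "degree_day_params"))
  spawn_doy <- round(spawn_doy)
  daily <- daily_temperatures(temps)
  if (spawn_doy < min(daily$doy) || spawn_doy >= max(daily$doy)) {
    stop("temperature series does not cover the spawn day", call. = FALSE)
  }
  after <- daily[daily$doy > spawn_doy, , drop = FALSE]
  inc <- pmax(0, after$temp_c - params$threshold)
  cum <- cumsum(inc)
  hit <- which(cum >= params$heat_sum)
  if (!length(hit)) {
    stop(errorCondition(
      sprintf("no hatch: heat sum %.1f not reached by day %d",
              params$heat_sum, max(daily$doy)),
      class = c("phenomatch_no_hatch", "error", "condition")))
  }
  as.integer(after$doy[hit[1L]] - spawn_doy)
}

#' Propagate a spawning distribution to larval-hatching phenology
#'
#' The peak hatch day is the hatch day of a spawner at the fitted spawning
#' peak mu; the hatching-period duration LS is the span between the hatch
#' days of spawners at mu - 2 sigma and mu + 2 sigma (the same 95%
#' definition as the spawning duration). Each spawn quantile is rounded to
#' the nearest day before degree-day accumulation. Under constant
#' temperature every spawner is shifted by the same number of days, so the
#' hatch peak is the spawn peak plus the development time and LS equals the
#' spawning duration; within-season warming compresses LS because later
#' spawners develop faster.
#'
#' A Monte-Carlo mode draws individual spawn days from the fitted Gaussian
#' and measures the same quantities from the simulated hatch days
#' (duration as the span between the 2.3% and 97.7% quantiles); it exists
#' to validate the quantile propagation, not to replace it.
#'
#' @param spawn A [fit_normal_phenology()] result, or any list with
#'   elements `mu` and `sigma` (and optionally `year`).
#' @param temps Data frame with columns `doy`, `temp_c` for the same year.
#' @param params A [degree_day_params()].
#' @param method `"quantile"` (default) or `"monte-carlo"`.
#' @param n_sim Number of simulated spawners for the Monte-Carlo mode.
#' @param seed Seed for the Monte-Carlo mode.
#' @return An object of class `hatch_phenology`: list with `peak` (hatch
#'   day of year), `duration` (days, > 0), `spawn_peak`, `spawn_duration`,
#'   `year`.
#' @export
hatch_phenology <- function(spawn, temps, params = degree_day_params(),
                            method = c("quantile", "monte-carlo"),
                            n_sim = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(spawn$mu), is.numeric(spawn$sigma), spawn$sigma > 0)
  if (method == "quantile") {
    qdays <- round(spawn$mu + c(-2, 0, 2) * spawn$sigma)
    hatch <- vapply(qdays, function(d) {
      d + days_to_hatch(temps, d, params)
    }, numeric(1))
    peak <- hatch[2L]
    duration <- hatch[3L] - hatch[1L]
  } else {
    local_rng(seed)
    sd_days <- round(stats::rnorm(n_sim, spawn$mu, spawn$sigma))
    hatch <- vapply(sd_days, function(d) {
      d + days_to_hatch(temps, d, params)
    }, numeric(1))
    peak <- unname(stats::median(hatch))
    qs <- stats::quantile(hatch, stats::pnorm(c(-2, 2)), names = FALSE)
    duration <- qs[2L] - qs[1L]
  }
  if (duration <= 0) {
    stop("degenerate hatching period: non-positive duration", call. = FALSE)
  }
  structure(list(peak = peak, duration = duration,
                 spawn_peak = spawn$mu, spawn_duration = 4 * spawn$sigma,
                 year = spawn$year %||% NA_integer_),
            class = "hatch_phenology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predator-prey phenological match/mismatch index
#'
#' The signed day difference between the prey (zooplankton) abundance peak
#' and the predator larval hatching peak: `PM = zooplankton peak - hatch
#' peak`. Positive values mean larvae hatch before the prey peak. With the
#' fitted recruitment coefficients this convention puts the
#' recruitment-maximizing mismatch at a positive value (hatching roughly
#' ten days before the prey peak) under low competition/cannibalism.
#'
#' @param hatch A [hatch_phenology()] result.
#' @param zoop A [fit_normal_phenology()] result for the zooplankton
#'   series of the same year.
#' @return A one-row data frame with columns `year`, `pm_days`.
#' @export
mismatch_index <- function(hatch, zoop) {
  stopifnot(inherits(hatch, "hatch_phenology"))
  yh <- hatch$year
  yz <- zoop$year %||% NA_integer_
  if (!is.na(yh) && !is.na(yz) && yh != yz) {
    stop(sprintf("year mismatch: hatch is %s, zooplankton is %s", yh, yz),
         call. = FALSE)
  }
  data.frame(year = if (!is.na(yh)) yh else yz,
             pm_days = zoop$mu - hatch$peak)
}
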