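# End-to-end synthetic lake system: daily temperature, weekly spawner
# catches, zooplankton series and yearly covariates with recruitment
# generated from the recruitment model, internally consistent so the full
# pipeline (phenology -> hatching -> mismatch -> regression) can be run
# and checked against the generative truth.

#' Simulate a complete lake monitoring data set
#'
#' Generates, for a span of years: a daily water-temperature record with a
#' warming trend; weekly spawner catches whose Gaussian spawning peak
#' advances and narrows over time (the observed pattern in the lake
#' system: roughly a two-week advance and a one-week shortening over four
#' decades); a weekly zooplankton series whose peak advances faster than
#' spawning, so the match/mismatch index shrinks from three-to-four weeks
#' to near zero; and yearly covariates (spawner number, mean spawner size,
#' age-3+ abundance with a truncation-induced drop, winter temperature,
#' disease flag). True hatch timing is obtained by propagating the true
#' spawning peaks through the degree-day model with the generated
#' temperatures, and recruitment is then drawn from the recruitment
#' regression at the supplied generative coefficients.
#'
#' @param years Years to simulate.
#' @param truth A [truth_params()] used for recruitment.
#' @param truncation_year Year of the demographic truncation (disease
#'   flag switches on; age-3+ abundance drops).
#' @param seed Integer seed.
#' @return A list of data frames: `temperature` (year, doy, temp_c),
#'   `catches` (year, doy, count), `zooplankton` (year, doy, count),
#'   `yearly` (year, spawners, mean_size_mm, age3plus, winter_temp_c,
#'   disease, recruits), and `truth` (the per-year true peaks, durations
#'   and mismatch used to generate recruitment).
#' @export
simulate_lake <- function(years = 1969:2008, truth = truth_params(),
                          truncation_year = 1976, seed = 1L) {
  local_rng(seed)
  ny <- length(years)
  y0 <- years[1L]
  sub <- sample.int(2^30, 6L)

  temperature <- gen_temperature(
    temperature_config(annual_mean = 9, amplitude = 6.5, peak_doy = 210,
                       trend = 0.03, noise_sd = 0.5, years = years),
    seed = sub[1L])

  elapsed <- years - y0
  spawn_peak <- 140 - 0.35 * elapsed + stats::rnorm(ny, 0, 1.5)
  spawn_sigma <- pmax(7 - 0.05 * elapsed + stats::rnorm(ny, 0, 0.4), 3)
  spawners <- stats::rlnorm(ny, log(30000), 0.4)
  zoop_peak <- 179 - 1.0 * elapsed + stats::rnorm(ny, 0, 3)
  post <- years >= truncation_year
  age3plus <- stats::rlnorm(ny, ifelse(post, log(12000), log(30000)), 0.4)
  winter_temp <- stats::rnorm(ny, 4, 1)
  mean_size <- ifelse(post, 165, 205) + stats::rnorm(ny, 0, 8)

  catch_seeds <- sample.int(2^30, ny)
  zoop_seeds <- sample.int(2^30, ny)
  catches <- do.call(rbind, lapply(seq_len(ny), function(i) {
    gen_spawner_catches(
      spawn_config(peak_doy = spawn_peak[i], sigma = spawn_sigma[i],
                   n_fish = round(spawners[i])),
      year = years[i], seed = catch_seeds[i])
  }))
  zooplankton <- do.call(rbind, lapply(seq_len(ny), function(i) {
    gen_zooplankton(peak = zoop_peak[i], sigma = 12, amplitude = 500,
                    noise = "poisson", year = years[i],
                    seed = zoop_seeds[i])
  }))

  # true hatch phenology from the true spawning curves and temperatures
  hatch <- lapply(seq_len(ny), function(i) {
    temps <- temperature[temperature$year == years[i], ]
    hatch_phenology(list(mu = spawn_peak[i], sigma = spawn_sigma[i],
                         year = years[i]), temps)
  })
  hatch_peak <- vapply(hatch, `[[`, numeric(1), "peak")
  hatch_dur <- vapply(hatch, `[[`, numeric(1), "duration")
  pm <- zoop_peak - hatch_peak

  pred <- data.frame(year = years, PM = pm, LS = hatch_dur, S = spawners,
                     CA = age3plus, WT = winter_temp)
  recruits <- gen_recruitment(pred, truth, seed = sub[6L])

  yearly <- data.frame(year = years, spawners = spawners,
                       mean_size_mm = mean_size, age3plus = age3plus,
                       winter_temp_c = winter_temp,
                       disease = as.integer(post), recruits = recruits)
  truth_tab <- data.frame(year = years, spawn_peak = spawn_peak,
                          spawn_sigma = spawn_sigma,
                          hatch_peak = hatch_peak,
                          hatch_duration = hatch_dur,
                          zoop_peak = zoop_peak, pm = pm)
  list(temperature = temperature, catches = catches,
       zooplankton = zooplankton, yearly = yearly, truth = truth_tab)
}

#' Write a simulated lake data set as CSV files
#'
#' Writes `temperature.csv`, `catches.csv`, `zooplankton.csv` and
#' `yearly.csv` into a directory.
#'
#' @param sim A [simulate_lake()] result.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_lake_csv <- function(sim, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c(temperature = "temperature.csv", catches = "catches.csv",
             zooplankton = "zooplankton.csv", yearly = "yearly.csv")
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(outdir, files[[nm]])
    utils::write.csv(sim[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
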