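test_that("temperature generator obeys its closed-form limits", {
  # constant limit: no seasonality, trend or noise
  cfg <- temperature_config(annual_mean = 10, amplitude = 0, trend = 0,
                            noise_sd = 0, years = 2000:2002)
  tt <- gen_temperature(cfg, seed = 1)
  expect_equal(unique(tt$temp_c), 10)
  expect_equal(nrow(tt), 3 * 365)

  # noiseless seasonal extremum at the configured peak day
  cfg <- temperature_config(annual_mean = 8, amplitude = 5, peak_doy = 200,
                            trend = 0, noise_sd = 0, years = 2000)
  tt <- gen_temperature(cfg, seed = 1)
  expect_equal(tt$doy[which.max(tt$temp_c)], 200)
  expect_equal(max(tt$temp_c), 13)

  # linear warming trend: 0.05 deg/yr over 40 years -> +1.95 in yearly mean
  cfg <- temperature_config(annual_mean = 9, amplitude = 6, trend = 0.05,
                            noise_sd = 0, years = 1970:2009)
  tt <- gen_temperature(cfg, seed = 1)
  m <- tapply(tt$temp_c, tt$year, mean)
  expect_equal(unname(m[["2009"]] - m[["1970"]]), 1.95, tolerance = 1e-12)

  expect_error(temperature_config(years = integer(0)), "non-empty")
  expect_error(temperature_config(amplitude = -1), ">= 0")
})

test_that("spawner catches are conserved and follow Gaussian bin masses", {
  # conservation across random configs
  for (s in 1:5) {
    cfg <- spawn_config(peak_doy = 120 + 10 * s, sigma = 3 + s,
                        n_fish = 1000 * s)
    expect_equal(sum(gen_spawner_catches(cfg, seed = s)$count),
                 1000L * s)
  }

  # degenerate spread with the peak at a bin centre puts every fish there
  cc <- gen_spawner_catches(spawn_config(peak_doy = 137, sigma = 0.1,
                                         n_fish = 500), seed = 3)
  expect_equal(cc$count[cc$doy == 137], 500L)
  expect_equal(sum(cc$count[cc$doy != 137]), 0L)

  # bin proportions match Gaussian CDF differences within multinomial error
  n_fish <- 100000
  cc <- gen_spawner_catches(spawn_config(135, 7, n_fish), seed = 42)
  mass <- pnorm(cc$doy + 3.5, 135, 7) - pnorm(cc$doy - 3.5, 135, 7)
  p <- mass / sum(mass)
  obs <- cc$count / n_fish
  tol <- 4 * sqrt(p * (1 - p) / n_fish) + 1e-9
  expect_true(all(abs(obs - p) < tol))

  expect_error(spawn_config(sigma = 0), "sigma")
  expect_error(spawn_config(n_fish = -5), ">= 0")
})

test_that("zooplankton curve peaks at the configured day and is symmetric", {
  z <- gen_zooplankton(peak = 165, sigma = 12, amplitude = 400,
                       noise = "none", days = 165 + (-56:56), seed = 1)
  expect_equal(z$doy[which.max(z$count)], 165)
  # symmetry about the peak
  left <- z$count[z$doy < 165]
  right <- rev(z$count[z$doy > 165])
  expect_equal(left, right)
  expect_error(gen_zooplankton(peak = 165, sigma = 0), "sigma")
})

test_that("recruitment generator reproduces the regression's closed forms", {
  # constant predictors => all centred terms zero => R = exp(intercept)
  rec <- data.frame(year = 1:10, PM = 5, LS = 14, S = 30000, CA = 20000,
                    WT = 4)
  tp <- truth_params(sigma_eps = 0)
  r <- gen_recruitment(rec, tp, seed = 1)
  expect_equal(r, rep(exp(11.4828), 10), tolerance = 1e-12)
  expect_equal(r[1], 97030, tolerance = 1e-4)

  # log-linearity: adding log(2) to the intercept doubles every count
  tp2 <- truth_params(beta0 = 11.4828 + log(2), sigma_eps = 0)
  expect_equal(gen_recruitment(rec, tp2, seed = 1), 2 * r,
               tolerance = 1e-12)

  # under D = low, expected recruitment peaks at centred PM = -b2/(2 b3_low)
  pm_grid <- seq(-40, 60, by = 0.005)
  rec <- data.frame(year = seq_along(pm_grid), PM = pm_grid, LS = 14,
                    S = 30000, CA = 20000, WT = 4)
  r <- gen_recruitment(rec, tp, seed = 1)
  vertex <- -tp$beta2 / (2 * tp$beta3_low)
  centred_argmax <- pm_grid[which.max(r)] - mean(pm_grid)
  expect_equal(centred_argmax, vertex, tolerance = 0.01)
  expect_equal(vertex, 9.197, tolerance = 1e-3)

  # missing predictor errors name the year and the field
  rec$CA[3] <- NA
  expect_error(gen_recruitment(rec, tp, seed = 1), "'CA' in year 3")
  expect_error(truth_params(sigma_eps = -1), ">= 0")
})

test_that("two-regime abundance generator matches its configuration", {
  reg <- abundance_regime(split_year = 1976, mean_pre = 4000,
                          mean_post = 6000, sdlog_pre = 0, sdlog_post = 0)
  ab <- gen_abundance(reg, n_years = 30, start_year = 1960, seed = 1)
  expect_equal(unique(ab$abundance[ab$year < 1976]), 4000)
  expect_equal(unique(ab$abundance[ab$year >= 1976]), 6000)

  ab <- gen_abundance(abundance_regime(), n_years = 60, start_year = 1946,
                      seed = 9)
  expect_true(all(ab$abundance > 0))
  expect_error(gen_abundance(abundance_regime(split_year = 2050), 30,
                             start_year = 1960, seed = 1), "boundary")
  expect_error(abundance_regime(sdlog_pre = -0.1), ">= 0")
})

test_that("all generators are deterministic given a seed", {
  pairs <- list(
    function(s) gen_temperature(temperature_config(years = 2000:2001), s),
    function(s) gen_spawner_catches(spawn_config(), seed = s),
    function(s) gen_zooplankton(165, 12, noise = "poisson", seed = s),
    function(s) gen_predictors(20, seed = s),
    function(s) gen_abundance(abundance_regime(), 40, 1946, seed = s),
    function(s) simulate_lake(years = 1990:1994, seed = s)$yearly)
  for (g in pairs) {
    expect_identical(g(7), g(7))
    expect_false(identical(g(7), g(8)))
  }
})

test_that("generators leave the caller's random state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_predictors(10, seed = 99))
  expect_identical(.Random.seed, before)
})
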