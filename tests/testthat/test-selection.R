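test_that("leave-one-year-out CV matches brute-force hand computation", {
  # noiseless linear data predicts perfectly out of sample
  rec <- data.frame(x = 1:12, y = 3 + 2 * (1:12), year = 1:12)
  spec <- model_spec("y", list(ms_term("x")))
  expect_equal(loo_cv_rmse(rec, spec), 0, tolerance = 1e-10)

  # three points, simple line: hand-computed fold errors are 2, -1, 2
  rec <- data.frame(x = c(0, 1, 2), y = c(0, 1, 0), year = 1:3)
  expect_equal(loo_cv_rmse(rec, spec), sqrt(3), tolerance = 1e-10)
})

test_that("fixed-design CV equals the closed-form PRESS statistic", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(12:25, 1)
    rec <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = runif(n))
    rec$y <- rnorm(n)
    spec <- model_spec("y", list(ms_term("x1"), ms_term("x2"),
                                 ms_term("x3", 2)))
    fit <- fit_model(rec, spec)
    expect_equal(loo_cv_rmse(rec, spec, recentre = FALSE),
                 press_rmse(fit), tolerance = 1e-10)
  }
})

test_that("fold-wise recentring changes nothing for affine-invariant designs", {
  # without dummy splits, OLS predictions are invariant to centring, so
  # both CV modes agree; with a median dummy they may differ
  rec <- toy_records(30, p = 2, noise_sd = 0.5)
  spec <- toy_spec(2)
  expect_equal(loo_cv_rmse(rec, spec, recentre = TRUE),
               loo_cv_rmse(rec, spec, recentre = FALSE), tolerance = 1e-10)
})

test_that("backward selection keeps active terms and drops noise terms", {
  rec <- toy_records(200, p = 6, active = c(x1 = 2, x2 = -1.5),
                     noise_sd = 0.1, seed = 3)
  tr <- backward_select(rec, toy_spec(6))
  final <- vapply(tr$final_spec$terms, `[[`, character(1), "var")
  expect_setequal(final, c("x1", "x2"))

  # the accepted-step CV values never increase
  expect_true(all(diff(tr$steps$cv_rmse) <= 1e-12))
})

test_that("pure-noise responses collapse to the intercept-only model", {
  # with pure noise, CV-based deletion keeps a spurious term with
  # non-vanishing probability, so the intercept-only collapse is a
  # majority outcome, not a certainty; checked with two noise candidates
  hits <- 0L
  for (s in 1:40) {
    rec <- toy_records(60, p = 2, active = c(x1 = 0), noise_sd = 1,
                       seed = 100 + s)
    tr <- backward_select(rec, toy_spec(2))
    if (length(tr$final_spec$terms) == 0L) hits <- hits + 1L
  }
  expect_gt(hits, 20L)  # majority of seeds
})

test_that("selection respects marginality and demotes interactions first", {
  rec <- gen_year_records(120, seed = 12)
  full <- preset_full_specs()$recruitment
  cands <- phenomatch:::admissible_deletions(full)
  labels <- vapply(cands, `[[`, character(1), "label")
  # S main effect is protected while S^2 remains; WT while WT^2 remains
  expect_false("drop S" %in% labels)
  expect_false("drop WT" %in% labels)
  # interactions are removable by demotion to main effects
  expect_true("drop LS:D interaction" %in% labels)
  expect_true("drop PM^2:D interaction" %in% labels)

  # demoting an interaction whose main effect already exists merges them
  demoted <- cands[[which(labels == "drop PM:D interaction")]]$spec
  lab2 <- vapply(demoted$terms, phenomatch:::term_label, character(1))
  expect_equal(sum(lab2 == "PM"), 1L)
})

test_that("AICc follows the small-sample-corrected formula", {
  # n = 10, RSS = 2.5, two coefficients + error variance: k = 3
  fake <- structure(list(n = 10L, k = 2L, rss = 2.5), class = "fit_result")
  expect_equal(aicc(fake), 10 * log(0.25) + 6 + 4, tolerance = 1e-12)
  expect_equal(aicc(fake), -3.8629, tolerance = 1e-4)

  # the correction vanishes as n grows at fixed k
  big <- structure(list(n = 1e6L, k = 2L, rss = 2.5e5),
                   class = "fit_result")
  aic <- big$n * log(big$rss / big$n) + 2 * 3
  expect_lt(abs(aicc(big) - aic), 1e-4)

  expect_error(aicc(structure(list(n = 4L, k = 2L, rss = 1),
                              class = "fit_result")), "n > k")
})

test_that("AICc agrees with CV selection on strongly identified data", {
  rec <- toy_records(200, p = 5, active = c(x1 = 2, x2 = -1.5),
                     noise_sd = 0.1, seed = 21)
  tr <- backward_select(rec, toy_spec(5))
  tab <- selection_aicc(rec, tr)
  expect_equal(which.min(tab$aicc), nrow(tab))  # final model is AICc-best
})

test_that("residual diagnostics flag the failures they are built to catch", {
  # perfectly alternating residuals have lag-1 autocorrelation near -1
  e <- rep(c(1, -1), 25)
  fake <- structure(list(residuals = e, fitted = rnorm(50), n = 50L),
                    class = "fit_result")
  d <- residual_diagnostics(fake)
  expect_equal(d$statistic[d$check == "autocorrelation"], -1,
               tolerance = 0.05)
  expect_false(d$pass[d$check == "autocorrelation"])

  # strong AR(1) residuals fail the autocorrelation check
  set.seed(5)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 200))
  fake <- structure(list(residuals = ar, fitted = rnorm(200), n = 200L),
                    class = "fit_result")
  expect_false(residual_diagnostics(fake)$pass[1])

  # i.i.d. Gaussian residuals pass all three checks about 95% of the time
  passes <- matrix(NA, 60, 3)
  for (s in 1:60) {
    set.seed(1000 + s)
    fake <- structure(list(residuals = rnorm(1000), fitted = rnorm(1000),
                           n = 1000L), class = "fit_result")
    passes[s, ] <- residual_diagnostics(fake)$pass
  }
  rates <- colMeans(passes)
  expect_true(all(rates >= 0.85))

  expect_error(
    residual_diagnostics(structure(list(residuals = rep(0, 20),
                                        fitted = rnorm(20)),
                                   class = "fit_result")),
    "degenerate")
  expect_error(
    residual_diagnostics(structure(list(residuals = rnorm(5),
                                        fitted = rnorm(5)),
                                   class = "fit_result")),
    "at least 8")
})
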