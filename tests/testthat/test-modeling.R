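test_that("design construction centres, splits and partitions correctly", {
  rec <- data.frame(year = 1:4, CA = c(10, 20, 30, 40),
                    LS = c(12, 14, 16, 18), R = c(100, 200, 300, 400))
  spec <- model_spec("R", list(ms_term("LS", by = "D")),
                     log_response = TRUE,
                     dummy = list(var = "CA", rule = "median"))
  d <- build_design(rec, spec)

  # the median rule: {10,20,30,40} -> median 25 -> low, low, high, high
  expect_equal(d$dummy_cut, 25)
  expect_equal(d$X[, "LS:Dlow"] != 0, c(TRUE, TRUE, FALSE, FALSE))

  # interaction columns are disjoint
  expect_equal(d$X[, "LS:Dlow"] * d$X[, "LS:Dhigh"], rep(0, 4))

  # the two interaction columns add up to the centred predictor
  expect_equal(d$X[, "LS:Dlow"] + d$X[, "LS:Dhigh"], rec$LS - mean(rec$LS))
})

test_that("centred columns have mean zero and powers follow centring", {
  rec <- gen_year_records(80, seed = 4)
  spec <- preset_specs()$recruitment
  d <- build_design(rec, spec)
  # every linear centred column has mean zero
  for (col in c("PM", "CA", "WT")) {
    expect_lt(abs(mean(d$X[, col])), 1e-10)
  }
  # quadratics are squares of the centred variable, not centred squares
  expect_equal(d$X[, "S^2"], (rec$S - mean(rec$S))^2)
  # interaction levels: together they reconstruct the centred predictor
  expect_equal(d$X[, "LS:Dlow"] + d$X[, "LS:Dhigh"],
               rec$LS - mean(rec$LS))
})

test_that("missing fields and values are reported by name and year", {
  rec <- gen_year_records(20, seed = 1)
  spec <- preset_specs()$recruitment
  expect_error(build_design(rec[, setdiff(names(rec), "WT")], spec),
               "missing field 'WT'")
  rec$PM[7] <- NA
  expect_error(build_design(rec, spec), "'PM' \\(year 7\\)")
  rec2 <- gen_year_records(20, seed = 1)
  rec2$WT <- 4
  expect_error(build_design(rec2, spec), "constant predictor 'WT'")
})

test_that("OLS reproduces exact fits and classical diagnostics", {
  # exact line through three points
  rec <- data.frame(x = c(0, 1, 2), y = c(1, 3, 5))
  fit <- fit_model(rec, model_spec("y", list(ms_term("x")), centre = FALSE))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)

  # leverages lie in [0,1] and sum to the number of coefficients
  rec <- gen_year_records(60, seed = 2)
  fit <- fit_model(rec, preset_specs()$recruitment)
  expect_true(all(fit$leverage >= 0 & fit$leverage <= 1))
  expect_equal(sum(fit$leverage), fit$k, tolerance = 1e-8)
  expect_lt(fit$k, fit$n)

  # cross-check estimates and standard errors against stats::lm
  X <- fit$design$X
  ref <- lm(fit$design$y ~ X - 1)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$se,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly naming the columns", {
  rec <- data.frame(x1 = rnorm(10))
  rec$x2 <- 2 * rec$x1
  rec$y <- rnorm(10)
  spec <- model_spec("y", list(ms_term("x1"), ms_term("x2")))
  expect_error(fit_model(rec, spec), "collinear")
})

test_that("fitting synthetic data recovers the generative coefficients", {
  # single large-sample check; the replicated recovery experiment is in
  # the acceptance suite
  tp <- truth_params()
  rec <- gen_year_records(2000, tp, seed = 31)
  fit <- fit_model(rec, preset_specs()$recruitment)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$se, fit$coefficients$term)
  truth <- c("(Intercept)" = tp$beta0, "LS:Dlow" = tp$beta1_low,
             "LS:Dhigh" = tp$beta1_high, "PM" = tp$beta2,
             "PM^2:Dlow" = tp$beta3_low, "PM^2:Dhigh" = tp$beta3_high,
             "S^2" = tp$beta4, "CA" = tp$beta5, "WT" = tp$beta6)
  for (nm in names(truth)) {
    expect_lt(abs(est[[nm]] - truth[[nm]]), 4 * se[[nm]])
  }
  # interaction contrast: the LS effect is stronger at low competition
  expect_gt(est[["LS:Dlow"]], est[["LS:Dhigh"]])
})

test_that("preset model structures match the selected lake-system models", {
  specs <- preset_specs()
  rec <- gen_year_records(40, seed = 6)
  d <- build_design(rec, specs$recruitment)
  expect_identical(colnames(d$X),
                   c("(Intercept)", "LS:Dlow", "LS:Dhigh", "PM",
                     "PM^2:Dlow", "PM^2:Dhigh", "S^2", "CA", "WT"))

  # the disease-by-temperature interaction is a candidate only
  full <- preset_full_specs()
  lab <- function(sp) vapply(sp$terms, phenomatch:::term_label, character(1))
  expect_true("ST:D" %in% lab(full$peak_spawning))
  expect_false("ST:D" %in% lab(specs$peak_spawning))

  # all three selected specs build valid designs on synthetic records
  set.seed(9)
  yearly <- data.frame(
    PS = rnorm(30, 135, 4), LS = rnorm(30, 25, 3), MS = rnorm(30, 190, 15),
    S = rlnorm(30, log(30000), 0.4), P = rep(c(0, 1), each = 15),
    ST = rnorm(30, 8, 1), MT = rnorm(30, 11, 1))
  for (sp in specs[c("peak_spawning", "spawning_duration")]) {
    d <- build_design(yearly, sp)
    expect_equal(nrow(d$X), 30)
    expect_false(anyNA(d$X))
  }
  for (sp in full[c("peak_spawning", "spawning_duration")]) {
    expect_false(anyNA(build_design(yearly, sp)$X))
  }
})
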