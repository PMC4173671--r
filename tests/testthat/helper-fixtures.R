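# Shared fixtures built in code.

# A one-year constant-temperature record.
const_temps <- function(temp, days = 1:250) {
  data.frame(doy = days, temp_c = temp)
}

# Yearly records with i.i.d. standard-normal predictors x1..xp and a
# linear response; used for CV and selection tests.
toy_records <- function(n, p = 6, active = c(x1 = 2, x2 = -1.5),
                        noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("x", seq_len(p))
  eta <- 1
  for (v in names(active)) eta <- eta + active[[v]] * x[[v]]
  x$y <- eta + rnorm(n, 0, noise_sd)
  x$year <- seq_len(n)
  x
}

toy_spec <- function(p = 6) {
  model_spec("y", lapply(paste0("x", seq_len(p)), ms_term))
}

# Closed-form PRESS RMSE from a full fit (leave-one-out identity for a
# fixed design): residual / (1 - leverage).
press_rmse <- function(fit) {
  sqrt(mean((fit$residuals / (1 - fit$leverage))^2))
}
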