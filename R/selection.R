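# Leave-one-year-out cross-validation, backward model selection, AICc and
# residual diagnostics for the declarative linear models.

#' Leave-one-year-out cross-validated RMSE of a model spec
#'
#' For each year: (i) fit the model to the data with that year removed,
#' (ii) predict the held-out observation, (iii) take the prediction error
#' (predicted minus observed), (iv) repeat for all years, (v) return the
#' square root of the mean squared prediction error. Errors are on the
#' modelling scale (log recruits for a log-transformed response).
#'
#' By default the centring means and the dummy split point are recomputed
#' inside every training fold, so the held-out year is transformed on the
#' training scale (a strict out-of-sample contract). With
#' `recentre = FALSE` the full-sample centres and split are used in every
#' fold, in which case the result equals the closed-form PRESS statistic
#' computed from the full-fit residuals and leverages.
#'
#' @param records Data frame of yearly records (one row per year).
#' @param spec A [model_spec()].
#' @param recentre Recompute centres and the dummy split per fold?
#' @return The cross-validated root-mean-square prediction error.
#' @export
loo_cv_rmse <- function(records, spec, recentre = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(records)
  full <- build_design(records, spec)
  k <- ncol(full$X)
  if (n < k + 1L) {
    stop("leave-one-out CV needs every training fold to support the fit (n >= k + 1)",
         call. = FALSE)
  }
  err <- numeric(n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    dtr <- if (recentre) {
      build_design(train, spec)
    } else {
      build_design(train, spec, centres = full$centres,
                   dummy_cut = full$dummy_cut)
    }
    qrx <- qr(dtr$X)
    if (qrx$rank < ncol(dtr$X)) {
      lab <- if (!is.null(records$year)) records$year[i] else i
      stop(sprintf("rank-deficient training design in fold %s", lab),
           call. = FALSE)
    }
    beta <- qr.coef(qrx, dtr$y)
    dte <- build_design(records[i, , drop = FALSE], spec,
                        centres = dtr$centres, dummy_cut = dtr$dummy_cut)
    err[i] <- drop(dte$X %*% beta) - dte$y
  }
  sqrt(mean(err^2))
}

# Enumerate the admissible single deletions from a spec. Each candidate
# removes one term or demotes one dummy interaction to its main effect.
# Marginality: a main effect is not dropped while a quadratic or
# interaction in the same variable remains.
admissible_deletions <- function(spec) {
  terms <- spec$terms
  labs <- vapply(terms, term_label, character(1))
  out <- list()
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    if (!is.null(t$by)) {
      # demote interaction to main effect (merging with an existing main)
      nt <- terms
      nt[[i]]$by <- NULL
      nlabs <- vapply(nt, term_label, character(1))
      nt <- nt[!duplicated(nlabs)]
      out[[length(out) + 1L]] <- list(
        label = paste0("drop ", labs[i], " interaction"),
        rank = 3L,
        spec = model_spec(spec$response, nt, spec$log_response,
                          spec$dummy, spec$centre))
    } else {
      others <- terms[-i]
      same_var_higher <- any(vapply(others, function(o) {
        o$var == t$var && (o$power > t$power || !is.null(o$by))
      }, logical(1)))
      if (t$power == 1L && same_var_higher) next
      out[[length(out) + 1L]] <- list(
        label = paste0("drop ", labs[i]),
        rank = if (t$power == 2L) 2L else 1L,
        spec = model_spec(spec$response, others, spec$log_response,
                          spec$dummy, spec$centre))
    }
  }
  out
}

#' Backward model selection by leave-one-year-out cross-validation
#'
#' Starts from the full candidate model and at each step evaluates every
#' admissible single deletion (dropping one plain term, or demoting one
#' dummy interaction to its main effect); the deletion with the lowest
#' cross-validated RMSE is applied if it does not exceed the current
#' model's, otherwise selection stops. Main effects are never dropped
#' while a quadratic or interaction in the same variable remains, and ties
#' are broken in favour of higher-order terms, then alphabetically.
#'
#' @inheritParams loo_cv_rmse
#' @param full_spec The full candidate [model_spec()].
#' @return An object of class `selection_trace`: list with `steps` (data
#'   frame: `step`, `dropped`, `cv_rmse`, `n_terms`; step 0 is the full
#'   model), `specs` (the model at each step) and `final_spec`.
#' @export
backward_select <- function(records, full_spec, recentre = TRUE) {
  cur <- full_spec
  cur_cv <- loo_cv_rmse(records, cur, recentre = recentre)
  steps <- data.frame(step = 0L, dropped = NA_character_, cv_rmse = cur_cv,
                      n_terms = length(cur$terms))
  specs <- list(cur)
  step <- 0L
  repeat {
    cands <- admissible_deletions(cur)
    if (!length(cands)) break
    cvs <- vapply(cands, function(cand) {
      loo_cv_rmse(records, cand$spec, recentre = recentre)
    }, numeric(1))
    ranks <- vapply(cands, `[[`, integer(1), "rank")
    labels <- vapply(cands, `[[`, character(1), "label")
    best <- order(cvs, -ranks, labels)[1L]
    if (cvs[best] > cur_cv) break
    step <- step + 1L
    cur <- cands[[best]]$spec
    cur_cv <- cvs[best]
    steps <- rbind(steps, data.frame(step = step, dropped = labels[best],
                                     cv_rmse = cur_cv,
                                     n_terms = length(cur$terms)))
    specs <- c(specs, list(cur))
  }
  structure(list(steps = steps, specs = specs, final_spec = cur),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Backward selection by leave-one-year-out CV\n")
  print(x$steps, row.names = FALSE)
  cat("final model: ")
  print(x$final_spec)
  invisible(x)
}

#' Corrected Akaike information criterion for a Gaussian OLS fit
#'
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n - k - 1)`, with `k` counting the
#' regression coefficients (including the intercept) plus one for the
#' error variance.
#'
#' @param fit A [ols_fit()] result (any list with elements `n`, `k`
#'   counting the regression coefficients, and `rss`).
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  n <- fit$n
  k <- fit$k + 1L  # + error variance
  if (n <= k + 1L) {
    stop("AICc undefined: need n > k + 1 (k counts coefficients and the error variance)",
         call. = FALSE)
  }
  n * log(fit$rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc along a backward-selection path
#'
#' Fits every model visited by [backward_select()] and returns its AICc,
#' for cross-checking that the CV-selected model is also AICc-best.
#'
#' @param records Data frame of yearly records.
#' @param trace A [backward_select()] result.
#' @return Data frame with `step`, `n_terms`, `aicc`.
#' @export
selection_aicc <- function(records, trace) {
  stopifnot(inherits(trace, "selection_trace"))
  vals <- vapply(trace$specs, function(sp) aicc(fit_model(records, sp)),
                 numeric(1))
  data.frame(step = trace$steps$step, n_terms = trace$steps$n_terms,
             aicc = vals)
}

#' Residual diagnostics for a fitted model
#'
#' Three checks at the given significance level: lag-1 residual
#' autocorrelation (Ljung-Box test at lag 1, with the lag-1 sample
#' autocorrelation reported as the statistic), variance homogeneity (a
#' Breusch-Pagan-type auxiliary regression of squared residuals on fitted
#' values; statistic `n R^2` against chi-squared with 1 d.f.) and
#' normality (Shapiro-Wilk).
#'
#' @param fit A [ols_fit()] result with at least 8 residuals.
#' @param alpha Significance level for the pass/fail column.
#' @return An object of class `residual_diagnostics`: data frame with
#'   columns `check`, `statistic`, `p_value`, `pass`.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  e <- fit$residuals
  n <- length(e)
  if (n < 8L) stop("need at least 8 residuals", call. = FALSE)
  if (stats::sd(e) == 0) {
    stop("degenerate fit: residuals have zero variance", call. = FALSE)
  }
  r1 <- sum(e[-1L] * e[-n]) / sum(e^2)
  p_ac <- stats::Box.test(e, lag = 1, type = "Ljung-Box")$p.value
  if (stats::var(e^2) == 0) {
    # squared residuals are constant: trivially homogeneous
    bp <- 0
    p_bp <- 1
  } else {
    aux <- stats::lm(e2 ~ f, data = data.frame(e2 = e^2, f = fit$fitted))
    bp <- n * summary(aux)$r.squared
    p_bp <- stats::pchisq(bp, df = 1, lower.tail = FALSE)
  }
  sw <- stats::shapiro.test(if (n > 5000) e[seq_len(5000)] else e)
  out <- data.frame(
    check = c("autocorrelation", "homogeneity", "normality"),
    statistic = c(r1, bp, unname(sw$statistic)),
    p_value = c(p_ac, p_bp, sw$p.value))
  out$pass <- out$p_value > alpha
  structure(out, class = c("residual_diagnostics", "data.frame"))
}
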