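# Declarative linear-model structures: centred predictors, quadratic terms
# formed after centring, and low/high dummy interactions, matching the
# regression design used for the spawning-phenology and recruitment models.

#' Declare one model term
#'
#' @param var Name of the predictor column.
#' @param power 1 (linear) or 2 (quadratic; squared after centring).
#' @param by `NULL` for a plain term, or `"D"` to interact the term with
#'   the low/high dummy declared in the model spec, producing one column
#'   per dummy level.
#' @param continuous If `FALSE` the predictor is left uncentred (use for
#'   0/1 indicator predictors such as a disease flag).
#' @return A list describing the term, for use in [model_spec()].
#' @export
ms_term <- function(var, power = 1, by = NULL, continuous = TRUE) {
  stopifnot(is.character(var), length(var) == 1L, power %in% c(1, 2))
  if (!is.null(by) && !identical(by, "D")) {
    stop("the only supported interaction is the level dummy 'D'",
         call. = FALSE)
  }
  list(var = var, power = as.integer(power), by = by,
       continuous = isTRUE(continuous))
}

term_label <- function(t) {
  base <- if (t$power == 2L) paste0(t$var, "^2") else t$var
  if (is.null(t$by)) base else paste0(base, ":D")
}

#' Declare a linear-model structure
#'
#' A model spec records the response (optionally log-transformed), the
#' terms, the centring rule (continuous predictors are centred by their
#' in-sample mean before powers and interactions are formed) and the
#' definition of the low/high dummy used in interactions.
#'
#' @param response Name of the response column.
#' @param terms List of [ms_term()] entries.
#' @param log_response Model `log(response)` instead of the raw response?
#' @param dummy `NULL`, or `list(var =, rule =)` where `rule` is
#'   `"median"` (low where the variable is at or below its in-sample
#'   median) or `"flag"` (low where the 0/1 variable is zero). Required if
#'   any term has `by = "D"`.
#' @param centre Centre continuous predictors? Defaults to `TRUE`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, terms, log_response = FALSE, dummy = NULL,
                       centre = TRUE) {
  stopifnot(is.character(response), length(response) == 1L, is.list(terms))
  has_by <- any(vapply(terms, function(t) !is.null(t$by), logical(1)))
  if (has_by && is.null(dummy)) {
    stop("terms interact with 'D' but no dummy definition was given",
         call. = FALSE)
  }
  if (!is.null(dummy)) {
    stopifnot(is.character(dummy$var), dummy$rule %in% c("median", "flag"))
  }
  labels <- vapply(terms, term_label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate model terms: ", paste(labels[duplicated(labels)],
                                          collapse = ", "), call. = FALSE)
  }
  structure(list(response = response, terms = terms,
                 log_response = isTRUE(log_response), dummy = dummy,
                 centre = isTRUE(centre)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  resp <- if (x$log_response) paste0("log(", x$response, ")") else x$response
  cat(resp, "~", paste(vapply(x$terms, term_label, character(1)),
                       collapse = " + "), "\n")
  if (!is.null(x$dummy)) {
    cat(sprintf("  D: low/high split of %s by rule '%s'\n",
                x$dummy$var, x$dummy$rule))
  }
  invisible(x)
}

dummy_levels <- function(records, dummy, cut = NULL) {
  x <- records[[dummy$var]]
  if (is.null(x)) stop(sprintf("missing dummy field '%s'", dummy$var),
                       call. = FALSE)
  if (dummy$rule == "median") {
    if (is.null(cut)) cut <- stats::median(x)
    list(low = x <= cut, cut = cut)
  } else {
    list(low = x == 0, cut = 0)
  }
}

#' Build the design matrix and response for a model spec
#'
#' Continuous predictors are centred by their in-sample mean BEFORE powers
#' and interaction columns are formed; the dummy `D` is `low` where the
#' split variable is at or below its in-sample median (rule `"median"`).
#' For out-of-sample prediction, pass the `centres` and `dummy_cut`
#' computed on the training data so the held-out rows are transformed on
#' the training scale.
#'
#' @param records Data frame of yearly records.
#' @param spec A [model_spec()].
#' @param centres Named numeric vector of centring means; computed from
#'   `records` when `NULL`.
#' @param dummy_cut Dummy split point; computed from `records` when `NULL`.
#' @return An object of class `model_design`: list with `X` (matrix with
#'   intercept column), `y`, `centres`, `dummy_cut`, `spec`.
#' @export
build_design <- function(records, spec, centres = NULL, dummy_cut = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(records))
  fields <- unique(c(spec$response,
                     vapply(spec$terms, `[[`, character(1), "var"),
                     if (!is.null(spec$dummy)) spec$dummy$var))
  for (f in fields) {
    if (is.null(records[[f]])) {
      stop(sprintf("missing field '%s'", f), call. = FALSE)
    }
    bad <- which(!is.finite(records[[f]]))
    if (length(bad)) {
      yr <- if (!is.null(records$year)) records$year[bad[1L]] else bad[1L]
      stop(sprintf("missing value in field '%s' (year %s)", f, yr),
           call. = FALSE)
    }
  }

  cont <- unique(vapply(Filter(function(t) t$continuous, spec$terms),
                        `[[`, character(1), "var"))
  training <- is.null(centres)
  if (training) {
    if (spec$centre) {
      centres <- vapply(cont, function(v) mean(records[[v]]), numeric(1))
    } else {
      centres <- stats::setNames(numeric(length(cont)), cont)
    }
    for (v in unique(vapply(spec$terms, `[[`, character(1), "var"))) {
      if (stats::var(records[[v]]) == 0) {
        stop(sprintf("constant predictor '%s'", v), call. = FALSE)
      }
    }
  }

  lev <- NULL
  if (!is.null(spec$dummy)) {
    lev <- dummy_levels(records, spec$dummy, cut = dummy_cut)
  }

  n <- nrow(records)
  cols <- list("(Intercept)" = rep(1, n))
  for (t in spec$terms) {
    x <- records[[t$var]]
    if (t$continuous && t$var %in% names(centres)) {
      x <- x - centres[[t$var]]
    }
    base <- x^t$power
    lab <- if (t$power == 2L) paste0(t$var, "^2") else t$var
    if (is.null(t$by)) {
      cols[[lab]] <- base
    } else {
      cols[[paste0(lab, ":Dlow")]] <- base * as.numeric(lev$low)
      cols[[paste0(lab, ":Dhigh")]] <- base * as.numeric(!lev$low)
    }
  }
  X <- do.call(cbind, cols)

  y <- records[[spec$response]]
  if (spec$log_response) {
    if (any(y <= 0)) {
      stop(sprintf("response '%s' must be positive for log transform",
                   spec$response), call. = FALSE)
    }
    y <- log(y)
  }

  structure(list(X = X, y = y,
                 centres = centres,
                 dummy_cut = if (is.null(lev)) NULL else lev$cut,
                 spec = spec),
            class = "model_design")
}

#' Ordinary least-squares fit of a model design
#'
#' Classical OLS: coefficient estimates, standard errors, two-sided
#' t-based p-values (n - k degrees of freedom), R-squared, residuals and
#' leverage (hat-matrix diagonal).
#'
#' @param design A [build_design()] result.
#' @return An object of class `fit_result`: list with `coefficients`
#'   (data frame: `term`, `estimate`, `se`, `t`, `p`), `residuals`,
#'   `fitted`, `leverage`, `n`, `k`, `rss`, `r_squared`, `sigma`, and the
#'   `design`.
#' @export
ols_fit <- function(design) {
  stopifnot(inherits(design, "model_design"))
  X <- design$X
  y <- design$y
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) stop("need more observations than coefficients",
                   call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < k) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1L):k]]
    stop("rank-deficient design; collinear columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  lev <- rowSums((X %*% xtx_inv) * X)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(pval)),
    residuals = resid, fitted = fitted, leverage = lev,
    n = n, k = k, rss = rss,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma = sqrt(sigma2), design = design),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit: n = %d, k = %d, R-squared = %.3f, sigma = %.4f\n",
              x$n, x$k, x$r_squared, x$sigma))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Fit a model spec to yearly records
#'
#' Convenience wrapper: [build_design()] then [ols_fit()].
#'
#' @inheritParams build_design
#' @return A `fit_result`.
#' @export
fit_model <- function(records, spec) {
  ols_fit(build_design(records, spec))
}

#' The three selected lake-system model structures
#'
#' Returns the selected model specs: peak spawning (`PS ~ S + P + ST +
#' ST^2`), spawning duration (`LS ~ MS + S + MT + MT^2`), and recruitment
#' (`log(R) ~ LS:D + PM + PM^2:D + S^2 + CA + WT`, with `D` the low/high
#' competition/cannibalism dummy split at the median of CA). Continuous
#' predictors are centred; the disease flag `P` is not.
#'
#' @return Named list of [model_spec()] objects: `peak_spawning`,
#'   `spawning_duration`, `recruitment`.
#' @seealso [preset_full_specs()] for the pre-selection candidate models.
#' @export
preset_specs <- function() {
  list(
    peak_spawning = model_spec(
      response = "PS",
      terms = list(ms_term("S"), ms_term("P", continuous = FALSE),
                   ms_term("ST"), ms_term("ST", 2))),
    spawning_duration = model_spec(
      response = "LS",
      terms = list(ms_term("MS"), ms_term("S"),
                   ms_term("MT"), ms_term("MT", 2))),
    recruitment = model_spec(
      response = "R", log_response = TRUE,
      terms = list(ms_term("LS", by = "D"), ms_term("PM"),
                   ms_term("PM", 2, by = "D"), ms_term("S", 2),
                   ms_term("CA"), ms_term("WT")),
      dummy = list(var = "CA", rule = "median")))
}

#' Full candidate model structures before backward selection
#'
#' The starting points for backward selection: the peak-spawning candidate
#' adds a temperature-by-disease interaction (`ST:D` with `D` the disease
#' flag), the duration candidate likewise, and the recruitment candidate
#' includes both phenology-by-competition interactions plus the quadratic
#' spawner and temperature terms with their main effects.
#'
#' @return Named list of [model_spec()] objects.
#' @export
preset_full_specs <- function() {
  list(
    peak_spawning = model_spec(
      response = "PS",
      terms = list(ms_term("S"), ms_term("P", continuous = FALSE),
                   ms_term("ST", by = "D"), ms_term("ST", 2)),
      dummy = list(var = "P", rule = "flag")),
    spawning_duration = model_spec(
      response = "LS",
      terms = list(ms_term("MS"), ms_term("S"),
                   ms_term("P", continuous = FALSE),
                   ms_term("MT", by = "D"), ms_term("MT", 2)),
      dummy = list(var = "P", rule = "flag")),
    recruitment = model_spec(
      response = "R", log_response = TRUE,
      terms = list(ms_term("LS", by = "D"), ms_term("PM", by = "D"),
                   ms_term("PM", 2, by = "D"), ms_term("S"),
                   ms_term("S", 2), ms_term("CA"), ms_term("WT"),
                   ms_term("WT", 2)),
      dummy = list(var = "CA", rule = "median")))
}
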