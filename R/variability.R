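# Sliding-window coefficient of variation of a yearly abundance series,
# split into the periods before and after the demographic truncation.

#' Sliding-window coefficient of variation by period
#'
#' For each window length `w` and each period (years before the split year
#' versus the split year onward), computes the coefficient of variation
#' (sample standard deviation over mean) in every length-`w` window of
#' consecutive years, advancing one year at a time, and returns the mean
#' and standard error of the window CVs. The standard error across
#' overlapping windows ignores their autocorrelation, and is reported as a
#' descriptive error bar only. Periods shorter than a window are flagged,
#' not fabricated.
#'
#' @param abundance Data frame with columns `year` and `abundance`
#'   (all values > 0), or a numeric vector with `years` supplied.
#' @param split_year First year of the post period.
#' @param windows Integer window lengths in years (default 3 to 11).
#' @param years Year labels when `abundance` is a bare vector.
#' @return Data frame with columns `period` (`"pre"`/`"post"`), `w`,
#'   `mean_cv`, `se_cv`, `n_windows`, `flag` (`"ok"` or `"too_short"`).
#' @export
sliding_cv <- function(abundance, split_year, windows = 3:11,
                       years = NULL) {
  if (is.data.frame(abundance)) {
    if (is.null(abundance$year) || is.null(abundance$abundance)) {
      stop("abundance data frame needs 'year' and 'abundance' columns",
           call. = FALSE)
    }
    years <- abundance$year
    x <- abundance$abundance
  } else {
    x <- abundance
    if (is.null(years)) years <- seq_along(x)
  }
  if (any(x <= 0)) stop("abundances must be positive", call. = FALSE)
  if (any(windows < 2)) stop("window length must be at least 2",
                             call. = FALSE)
  ord <- order(years)
  years <- years[ord]
  x <- x[ord]

  one_period <- function(label, v) {
    rows <- lapply(windows, function(w) {
      if (length(v) < w) {
        return(data.frame(period = label, w = w, mean_cv = NA_real_,
                          se_cv = NA_real_, n_windows = 0L,
                          flag = "too_short"))
      }
      nw <- length(v) - w + 1L
      cvs <- vapply(seq_len(nw), function(j) {
        win <- v[j:(j + w - 1L)]
        stats::sd(win) / mean(win)
      }, numeric(1))
      data.frame(period = label, w = w, mean_cv = mean(cvs),
                 se_cv = if (nw > 1L) stats::sd(cvs) / sqrt(nw) else NA_real_,
                 n_windows = nw, flag = "ok")
    })
    do.call(rbind, rows)
  }

  rbind(one_period("pre", x[years < split_year]),
        one_period("post", x[years >= split_year]))
}
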