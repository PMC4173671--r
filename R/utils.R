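# Internal helpers shared across modules.

# Seed the RNG for the duration of the calling function, restoring the
# caller's random state afterwards, so generators take explicit seeds
# without touching global state.
local_rng <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  do.call(on.exit,
          list(as.call(list(restore)), add = TRUE),
          envir = env)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Validate a within-year series data frame and return it with the value
# column renamed to `value`. Days must be strictly increasing and in
# [1, 366].
as_daily_series <- function(series, value_col) {
  if (!is.data.frame(series)) {
    stop("series must be a data frame", call. = FALSE)
  }
  if (is.null(series$doy)) stop("series must have a 'doy' column",
                                call. = FALSE)
  if (is.null(series[[value_col]])) {
    stop(sprintf("series must have a '%s' column", value_col), call. = FALSE)
  }
  doy <- series$doy
  if (any(diff(doy) <= 0)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  if (any(doy < 1 | doy > 366)) {
    stop("days must lie in [1, 366]", call. = FALSE)
  }
  data.frame(year = if (is.null(series$year)) NA_integer_ else series$year,
             doy = doy, value = series[[value_col]])
}
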