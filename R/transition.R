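#' Growth curve container
#'
#' @param strain,replicate labels.
#' @param times hours since inoculation, strictly increasing.
#' @param od600 optical densities; strictly positive.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(strain, replicate, times, od600) {
  pk_assert(length(times) > 0, "empty time vector")
  pk_assert(length(times) == length(od600), "times/od600 length mismatch")
  pk_assert(all(diff(times) > 0), "times must be strictly increasing")
  pk_assert(all(od600 > 0), "od600 values must be positive")
  structure(list(strain = strain, replicate = replicate,
                 times = as.numeric(times), od600 = as.numeric(od600)),
            class = "growth_curve")
}

#' Production (A410) curve container
#'
#' @param strain,replicate labels.
#' @param times hours, strictly increasing; raw (since inoculation) unless
#'   `anchored = TRUE`, in which case they are relative to T0.
#' @param a410 absorbance at 410 nm; non-negative.
#' @param anchored logical flag: are `times` T0-anchored?
#' @return object of class `production_curve`.
#' @export
production_curve <- function(strain, replicate, times, a410, anchored = FALSE) {
  pk_assert(length(times) > 0, "empty time vector")
  pk_assert(length(times) == length(a410), "times/a410 length mismatch")
  pk_assert(all(diff(times) > 0), "times must be strictly increasing")
  pk_assert(all(a410 >= 0), "a410 values must be non-negative")
  structure(list(strain = strain, replicate = replicate,
                 times = as.numeric(times), a410 = as.numeric(a410),
                 anchored = isTRUE(anchored)),
            class = "production_curve")
}

## Slope and R^2 of log(OD) ~ time over one window (closed form; called many
## times, so no lm() overhead).
loglinear_fit <- function(t, logod) {
  n <- length(t)
  mx <- mean(t); my <- mean(logod)
  sxx <- sum((t - mx)^2)
  sxy <- sum((t - mx) * (logod - my))
  b <- sxy / sxx
  a <- my - b * mx
  fitted <- a + b * t
  sst <- sum((logod - my)^2)
  sse <- sum((logod - fitted)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  list(intercept = a, slope = b, r2 = r2)
}

#' Detect the exponential-to-stationary transition time (T0)
#'
#' Fits log(OD600) against time in every sliding window of `window_points`
#' consecutive observations, takes the window with the steepest slope among
#' those with R^2 >= `r2_min` as the exponential reference, and reports T0 as
#' the earliest time after that window at which the observed OD falls below
#' the extrapolated exponential line by more than `deviation_frac`
#' (relative), sustained for `run_length` consecutive points.
#'
#' Log-linear regression below the instrument's reliable range is noise
#' dominated (an additive OD error is huge relative to a small OD), so
#' candidate windows whose smallest OD falls below `od_min` are excluded
#' from the reference search.
#'
#' @param curve a [growth_curve()].
#' @param window_points points per sliding window (default 5).
#' @param r2_min minimum R^2 for a window to qualify as exponential
#'   (default 0.99).
#' @param deviation_frac relative OD shortfall that counts as deviation
#'   (default 0.05).
#' @param run_length consecutive deviating points required (default 3).
#' @param od_min smallest OD admitted into a reference window
#'   (default 0.05).
#' @return an object of class `transition_estimate` with fields `strain`,
#'   `replicate`, `t0` (hours since inoculation), `exp_rate` (1/h) and
#'   `fit_window` (start/end hours of the reference window).
#' @export
detect_transition_time <- function(curve, window_points = 5, r2_min = 0.99,
                                   deviation_frac = 0.05, run_length = 3,
                                   od_min = 0.05) {
  n <- length(curve$times)
  pk_assert(n >= 2 * window_points,
            "need at least 2*window_points observations")
  logod <- log(curve$od600)
  starts <- seq_len(n - window_points + 1L)
  fits <- lapply(starts, function(i) {
    idx <- i:(i + window_points - 1L)
    f <- loglinear_fit(curve$times[idx], logod[idx])
    f$min_od <- min(curve$od600[idx])
    f
  })
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  min_od <- vapply(fits, `[[`, numeric(1), "min_od")
  ok <- r2 >= r2_min & slope > 0 & min_od >= od_min
  if (!any(ok))
    pk_stop("no window attains the exponential-phase R^2 threshold",
            "no_exponential_phase")
  best <- which(ok)[which.max(slope[ok])]
  ref <- fits[[best]]
  win_end <- best + window_points - 1L
  after <- if (win_end < n) (win_end + 1L):n else integer(0)
  pred <- exp(ref$intercept + ref$slope * curve$times[after])
  dev <- (pred - curve$od600[after]) / pred > deviation_frac
  t0_idx <- NA_integer_
  if (length(dev) >= run_length) {
    runs <- which(vapply(seq_len(length(dev) - run_length + 1L), function(i)
      all(dev[i:(i + run_length - 1L)]), logical(1)))
    if (length(runs) > 0) t0_idx <- after[runs[1L]]
  }
  if (is.na(t0_idx))
    pk_stop("growth never deviates from the exponential reference",
            "no_transition")
  structure(list(strain = curve$strain, replicate = curve$replicate,
                 t0 = curve$times[t0_idx], exp_rate = ref$slope,
                 fit_window = c(curve$times[best], curve$times[win_end])),
            class = "transition_estimate")
}
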