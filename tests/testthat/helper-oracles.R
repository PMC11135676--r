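## Independent brute-force oracles, kept deliberately naive.

## Every-point neighbour comparison peak finder; plateaus count once at
## their leftmost point.
oracle_peaks <- function(signal) {
  n <- length(signal)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (signal[i] <= signal[i - 1]) next
    j <- i
    while (j < n && signal[j + 1] == signal[i]) j <- j + 1
    if (j < n && signal[j + 1] < signal[i]) out <- c(out, i)
  }
  out
}

## Exhaustive maximum-cardinality, minimum-total-|diff| assignment between
## two size lists under a tolerance.  Recursion over a's elements.
oracle_match <- function(a, b, tol) {
  best <- list(count = -1, cost = Inf)
  recurse <- function(i, used_b, count, cost) {
    if (i > length(a)) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    recurse(i + 1, used_b, count, cost)  # leave a[i] unmatched
    for (j in seq_along(b)) {
      if (used_b[j]) next
      d <- abs(a[i] - b[j])
      if (d <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, count + 1, cost + d)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, logical(length(b)), 0, 0)
  best
}

## Exhaustive-scan transition rule: every window via lm(), same selection
## and deviation rule as the package, no shortcuts.
oracle_t0 <- function(times, od, window_points = 5, r2_min = 0.99,
                      deviation_frac = 0.05, run_length = 3, od_min = 0.05) {
  n <- length(times)
  logod <- log(od)
  best_slope <- -Inf; best_end <- NA; best_fit <- NULL
  for (i in seq_len(n - window_points + 1)) {
    idx <- i:(i + window_points - 1)
    if (min(od[idx]) < od_min) next
    m <- stats::lm(y ~ t, data.frame(t = times[idx], y = logod[idx]))
    r2 <- summary(m)$r.squared
    sl <- stats::coef(m)[["t"]]
    if (r2 >= r2_min && sl > 0 && sl > best_slope) {
      best_slope <- sl; best_end <- max(idx); best_fit <- m
    }
  }
  if (is.na(best_end)) return(NA_real_)
  for (i in (best_end + 1):n) {
    run_ok <- TRUE
    for (k in i:(i + run_length - 1)) {
      if (k > n) { run_ok <- FALSE; break }
      pred <- exp(stats::predict(best_fit, data.frame(t = times[k])))
      if ((pred - od[k]) / pred <= deviation_frac) { run_ok <- FALSE; break }
    }
    if (run_ok) return(times[i])
  }
  NA_real_
}

## Exhaustive fine-grid scan for the production start rule.
oracle_start_time <- function(mutant, reference, t0, delta, grid_step,
                              t_min = 0, t_max = 40) {
  grid <- seq(t_min, t_max, by = grid_step)
  for (i in seq_len(length(grid) - 1)) {
    over1 <- gompertz_value(mutant, grid[i]) -
      gompertz_value(reference, grid[i]) > delta
    over2 <- gompertz_value(mutant, grid[i + 1]) -
      gompertz_value(reference, grid[i + 1]) > delta
    if (over1 && over2) return(grid[i] - t0)
  }
  NA_real_
}

## Numeric inflection-tangent duration: locate the steepest point on a dense
## grid, build the tangent there, and intersect it with y0 and K.
oracle_tangent_duration <- function(params) {
  f <- function(t) gompertz_value(params, t)
  h <- 1e-5
  slope_at <- function(t) (f(t + h) - f(t - h)) / (2 * h)
  # bracket the steepest point on a dense grid, then refine
  grid <- seq(params$lambda - 20, params$lambda + 100, length.out = 4000)
  i <- which.max(vapply(grid, slope_at, numeric(1)))
  opt <- stats::optimize(slope_at,
                         interval = grid[c(max(1, i - 2),
                                           min(length(grid), i + 2))],
                         maximum = TRUE, tol = 1e-10)
  tstar <- opt$maximum; s <- opt$objective; ystar <- f(tstar)
  t_y0 <- tstar + (params$y0 - ystar) / s
  t_K <- tstar + (params$K - ystar) / s
  t_K - t_y0
}

## Shared fixture: a modest trace pair + analysis, reused across tests.
pk_test_probe <- function() yvmc_probe()
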