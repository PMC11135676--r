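#' Fit the modified Gompertz model to an A410 time course
#'
#' Nonlinear least squares (Levenberg-Marquardt) with data-driven starting
#' values: y0 from the minimum, K from the maximum, mumax from the steepest
#' observed secant slope, lambda from the first time the signal rises above
#' y0 + 10% of the dynamic range.
#'
#' @param curve a [production_curve()].
#' @param range_floor minimum dynamic range (max - min A410) below which the
#'   fit is refused as degenerate (default 0.02 absorbance).
#' @return a `gompertz_fit`: the [gompertz_params()] plus `resid_sd`,
#'   `converged`, and the input labels.
#' @export
fit_gompertz <- function(curve, range_floor = 0.02) {
  t <- curve$times; y <- curve$a410
  pk_assert(length(y) >= 6, "need at least 6 observations")
  rng <- max(y) - min(y)
  if (rng < range_floor)
    pk_stop(sprintf("dynamic range %.4f below floor %.4f", rng, range_floor),
            "degenerate_fit")
  y0_init <- min(y)
  K_init <- max(y)
  sec <- diff(y) / diff(t)
  mumax_init <- max(sec)
  if (mumax_init <= 0) mumax_init <- rng / (max(t) - min(t))
  above <- which(y > y0_init + 0.1 * rng)
  lambda_init <- if (length(above) > 0) t[above[1L]] else mean(t)

  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (K - y0) * exp(-exp(mumax * exp(1) * (lambda - t) / (K - y0) + 1)),
      data = dat,
      start = list(y0 = y0_init, K = K_init, mumax = mumax_init,
                   lambda = lambda_init),
      lower = c(y0 = 0, K = y0_init + range_floor / 2, mumax = 1e-6,
                lambda = min(t) - (max(t) - min(t))),
      upper = c(y0 = K_init, K = 10 * K_init, mumax = Inf, lambda = max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    warning("Gompertz fit did not converge for ", curve$strain, "/",
            curve$replicate, "; returning starting values flagged unconverged")
    params <- gompertz_params(y0_init, K_init, mumax_init, lambda_init)
    resid_sd <- stats::sd(y - gompertz_value(params, t))
    converged <- FALSE
  } else {
    cf <- stats::coef(fit)
    params <- gompertz_params(cf[["y0"]], cf[["K"]], cf[["mumax"]],
                              cf[["lambda"]])
    resid_sd <- stats::sd(stats::resid(fit))
    converged <- fit$convInfo$isConv
  }
  structure(c(params,
              list(resid_sd = resid_sd, converged = converged,
                   strain = curve$strain, replicate = curve$replicate)),
            class = c("gompertz_fit", "gompertz_params"))
}

#' Production start time relative to T0
#'
#' The earliest time (on a regular grid, reported relative to T0) at which
#' the predicted mutant A410 exceeds the predicted reference (WT background)
#' A410 by more than `delta`, sustained for two consecutive grid points.
#'
#' @param mutant_fit,reference_fit [gompertz_params()] (or fits).
#' @param t0 transition time, hours since inoculation.
#' @param delta absorbance excess that counts as deviation.
#' @param grid_step grid resolution in hours (default 0.1).
#' @param t_min,t_max absolute time range scanned (hours since inoculation;
#'   defaults 0 and 40).
#' @return hours relative to T0 (negative = before the transition), or `NA`
#'   if the mutant never deviates.
#' @export
production_start_time <- function(mutant_fit, reference_fit, t0, delta,
                                  grid_step = 0.1, t_min = 0, t_max = 40) {
  grid <- seq(t_min, t_max, by = grid_step)
  excess <- gompertz_value(mutant_fit, grid) -
    gompertz_value(reference_fit, grid) > delta
  if (length(grid) >= 2) {
    sustained <- excess[-length(excess)] & excess[-1L]
    hit <- which(sustained)
  } else hit <- integer(0)
  if (length(hit) == 0) return(NA_real_)
  grid[hit[1L]] - t0
}

#' Summarize per-replicate kinetics for one strain
#'
#' Collects the four production parameters (start time relative to T0,
#' duration, maximum rate, maximum A410) across replicates and reports their
#' mean and SD.  Start times require a reference (WT-background) fit per
#' replicate; without one they are reported as `NA`.
#'
#' @param fits list of `gompertz_fit` for one strain (one per replicate).
#' @param t0s list of `transition_estimate`, matched to `fits` by position.
#' @param reference_fits optional list of reference `gompertz_fit` matched by
#'   position; used for start-time computation.
#' @param delta_floor minimum deviation threshold for the start time
#'   (absorbance, default 0.005); the threshold used is
#'   `max(delta_floor, 3 * reference resid_sd)`.
#' @param ... passed to [production_start_time()].
#' @return a `kinetic_summary`: strain, `replicate_n`, per-parameter mean and
#'   SD (`stats`, a data.frame), and the per-replicate values (`replicates`).
#' @export
summarize_strain <- function(fits, t0s, reference_fits = NULL,
                             delta_floor = 0.005, ...) {
  pk_assert(length(fits) >= 1, "need at least one replicate")
  pk_assert(length(fits) == length(t0s), "fits/t0s length mismatch")
  strains <- unique(vapply(fits, `[[`, character(1), "strain"))
  pk_assert(length(strains) == 1, "mixed strains in input")
  n <- length(fits)
  start <- rep(NA_real_, n)
  if (!is.null(reference_fits)) {
    pk_assert(length(reference_fits) == n, "reference_fits length mismatch")
    for (i in seq_len(n)) {
      delta <- max(delta_floor, 3 * reference_fits[[i]]$resid_sd)
      start[i] <- production_start_time(fits[[i]], reference_fits[[i]],
                                        t0 = t0s[[i]]$t0, delta = delta, ...)
    }
  }
  per <- data.frame(
    replicate = vapply(fits, function(f) as.character(f$replicate),
                       character(1)),
    start_time = start,
    duration = vapply(fits, production_duration, numeric(1)),
    max_rate = vapply(fits, `[[`, numeric(1), "mumax"),
    max_a410 = vapply(fits, `[[`, numeric(1), "K"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  params <- c("start_time", "duration", "max_rate", "max_a410")
  stats_df <- data.frame(
    parameter = params,
    mean = vapply(params, function(p) mean(per[[p]]), numeric(1)),
    sd = vapply(params, function(p)
      if (n > 1) stats::sd(per[[p]]) else 0, numeric(1)),
    n = n, row.names = NULL)
  structure(list(strain = strains, replicate_n = n, stats = stats_df,
                 replicates = per),
            class = "kinetic_summary")
}

#' Pairwise parameter comparisons across strains
#'
#' Two-sided Welch t-tests on per-replicate values of one kinetic parameter
#' for every strain pair, Bonferroni-corrected over the number of pairs.
#'
#' @param summaries list of `kinetic_summary`, one per strain.
#' @param parameter one of `"start_time"`, `"duration"`, `"max_rate"`,
#'   `"max_a410"`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with columns `strain_a`, `strain_b`, `raw_p`, `adj_p`,
#'   `significant`.
#' @export
compare_parameters <- function(summaries, parameter, alpha = 0.05) {
  pk_assert(length(summaries) >= 2, "need at least two strains")
  pk_assert(parameter %in% c("start_time", "duration", "max_rate",
                             "max_a410"), "unknown parameter")
  vals <- lapply(summaries, function(s) s$replicates[[parameter]])
  labs <- vapply(summaries, `[[`, character(1), "strain")
  if (any(vapply(vals, length, integer(1)) < 2))
    pk_stop("every strain needs >= 2 replicates", "invalid_input")
  pairs <- utils::combn(length(summaries), 2)
  raw <- apply(pairs, 2, function(ij) {
    x <- vals[[ij[1]]]; y <- vals[[ij[2]]]
    if (any(is.na(c(x, y)))) return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(1)  # no variance: treat as non-significant
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  })
  adj <- stats::p.adjust(raw, method = "bonferroni", n = ncol(pairs))
  data.frame(strain_a = labs[pairs[1, ]], strain_b = labs[pairs[2, ]],
             raw_p = raw, adj_p = adj,
             significant = !is.na(adj) & adj < alpha)
}
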