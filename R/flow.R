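#' Gating threshold from a negative control
#'
#' The threshold is the maximum fluorescence observed in the no-GFP control,
#' so that the control itself always gates to exactly 0% positive.
#'
#' @param control a [flow_sample()] with `is_control = TRUE`.
#' @return threshold in fluorescence units.
#' @export
gate_threshold <- function(control) {
  pk_assert(inherits(control, "flow_sample"), "control must be a flow_sample")
  pk_assert(control$is_control, "sample is not flagged as a control")
  pk_assert(length(control$events) >= 1, "empty control")
  max(control$events)
}

#' Percent GFP-positive for one sample
#'
#' Percent positive is 100 times the number of events strictly greater than
#' the threshold divided by the total number of events; the median is
#' computed over all events on the linear scale.
#'
#' @param sample a [flow_sample()].
#' @param threshold fluorescence threshold (from [gate_threshold()]).
#' @return a `gate_result`: `sample_id`, `strain`, `threshold`,
#'   `percent_positive` (0..100), `median_fluorescence`, `n_events`.
#' @export
percent_positive <- function(sample, threshold) {
  pk_assert(length(sample$events) >= 1, "empty sample")
  structure(list(sample_id = sample$sample_id, strain = sample$strain,
                 threshold = threshold,
                 percent_positive =
                   100 * mean(sample$events > threshold),
                 median_fluorescence = stats::median(sample$events),
                 n_events = length(sample$events)),
            class = "gate_result")
}

#' Summarize gating results across trials
#'
#' Per-strain mean and sample SD of percent positive and of the median
#' fluorescence.
#'
#' @param results list of `gate_result` objects.
#' @return data.frame with one row per strain: `strain`, `n_trials`,
#'   `mean_percent_positive`, `sd_percent_positive`, `mean_median_fluor`,
#'   `sd_median_fluor`.
#' @export
summarize_trials <- function(results) {
  pk_assert(length(results) >= 1, "no gating results")
  df <- data.frame(
    strain = vapply(results, `[[`, character(1), "strain"),
    pct = vapply(results, `[[`, numeric(1), "percent_positive"),
    med = vapply(results, `[[`, numeric(1), "median_fluorescence"))
  out <- do.call(rbind, lapply(split(df, df$strain), function(d) {
    data.frame(strain = d$strain[1], n_trials = nrow(d),
               mean_percent_positive = mean(d$pct),
               sd_percent_positive = if (nrow(d) > 1) stats::sd(d$pct) else 0,
               mean_median_fluor = mean(d$med),
               sd_median_fluor = if (nrow(d) > 1) stats::sd(d$med) else 0)
  }))
  rownames(out) <- NULL
  out
}
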