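#' Flow sample container
#'
#' @param sample_id,strain labels.
#' @param events fluorescence intensities (linear units), all finite.
#' @param is_control logical: no-GFP control sample?
#' @return object of class `flow_sample`.
#' @export
flow_sample <- function(sample_id, strain, events, is_control = FALSE) {
  pk_assert(length(events) >= 1, "need at least one event")
  pk_assert(all(is.finite(events)), "intensities must be finite")
  structure(list(sample_id = sample_id, strain = strain,
                 events = as.numeric(events),
                 is_control = isTRUE(is_control)),
            class = "flow_sample")
}

#' Generate a synthetic flow-cytometry sample
#'
#' Draws `n_events` fluorescence intensities from the preset's two-component
#' log10-normal mixture (the number of positive events is binomial in the
#' positive fraction).  Deterministic for a fixed seed.
#'
#' @param preset a [flow_preset()].
#' @param n_events number of events (>= 1).
#' @param seed integer RNG seed.
#' @param sample_id sample label (defaults to the preset name).
#' @return a [flow_sample()].
#' @export
generate_flow_sample <- function(preset, n_events, seed,
                                 sample_id = preset$name) {
  if (n_events < 1) pk_stop("n_events must be >= 1", "invalid_input")
  set.seed(seed)
  n_pos <- stats::rbinom(1, n_events, preset$positive_fraction)
  logv <- c(stats::rnorm(n_pos, preset$pos_log_mean, preset$pos_log_sd),
            stats::rnorm(n_events - n_pos, preset$neg_log_mean,
                         preset$neg_log_sd))
  flow_sample(sample_id, preset$name, 10^sample(logv),
              is_control = preset$is_control)
}
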