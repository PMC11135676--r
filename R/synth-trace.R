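#' Electropherogram trace container
#'
#' One capillary-electrophoresis trace with a sample channel and a co-run
#' size-ladder channel on a shared scan grid.
#'
#' @param scan strictly increasing integer scan indices.
#' @param sample_signal,ladder_signal per-scan fluorescence (equal lengths).
#' @param label `"with_protein"` or `"without_protein"`.
#' @return object of class `fa_trace`.
#' @export
fa_trace <- function(scan, sample_signal, ladder_signal, label) {
  pk_assert(all(diff(scan) > 0), "scan indices must be strictly increasing")
  pk_assert(length(scan) == length(sample_signal) &&
              length(scan) == length(ladder_signal),
            "channel length mismatch")
  pk_assert(label %in% c("with_protein", "without_protein"),
            "label must be with_protein or without_protein")
  structure(list(scan = as.integer(scan),
                 sample_signal = as.numeric(sample_signal),
                 ladder_signal = as.numeric(ladder_signal),
                 label = label),
            class = "fa_trace")
}

## Add Gaussian-shaped peaks (centers in scan units, heights, common sigma)
## onto a signal vector defined on integer scans 1..n.
add_peaks <- function(signal, centers, heights, sigma) {
  n <- length(signal)
  halfwin <- ceiling(6 * sigma)
  for (k in seq_along(centers)) {
    lo <- max(1L, floor(centers[k] - halfwin))
    hi <- min(n, ceiling(centers[k] + halfwin))
    if (lo > hi) next
    idx <- lo:hi
    signal[idx] <- signal[idx] +
      heights[k] * exp(-((idx - centers[k])^2) / (2 * sigma^2))
  }
  signal
}

#' Generate a with/without-protein electropherogram pair
#'
#' One Gaussian peak per probe position in the sample channel, at scan
#' positions regularly spaced in fragment size (optionally with a mild
#' quadratic curvature to exercise the size calibration), plus the size
#' ladder in a second channel.  Without-protein peak heights equal
#' `base_height` times a per-position log-normal jitter shared between the
#' two traces (mimicking sequence-dependent DNase I cutting preference);
#' with-protein heights are additionally attenuated inside the protein's
#' window and amplified at hypersensitive sites.  Both traces share the scan
#' grid.  Deterministic for a fixed seed.
#'
#' @param spec a [footprint_spec()].
#' @param probe a [probe_map()]; must contain the spec window.
#' @param peak_spacing_scans scans per bp (default 10).
#' @param peak_width_scans Gaussian peak SD in scans (default 1.2).
#' @param base_height nominal peak height, signal units (default 1000).
#' @param noise_sd additive per-scan noise SD (default 0).
#' @param seed integer RNG seed.
#' @param jitter_sd SD of the shared per-position log-normal height jitter
#'   (default 0; the study-condition default for noisy runs is 0.05).
#' @param ladder_sizes ladder fragment sizes in bp (default [liz500_sizes()]).
#' @param ladder_height ladder peak height (default `base_height`).
#' @param scan_offset scan index of the size-0 intercept (default 50).
#' @param curvature quadratic term of the scan-size map, scans/bp^2
#'   (default 0 = linear spacing).
#' @return list with elements `with` and `without`, both [fa_trace()].
#' @export
generate_trace_pair <- function(spec, probe, peak_spacing_scans = 10,
                                peak_width_scans = 1.2, base_height = 1000,
                                noise_sd = 0, seed = 1, jitter_sd = 0,
                                ladder_sizes = liz500_sizes(),
                                ladder_height = base_height,
                                scan_offset = 50, curvature = 0) {
  pos_tss <- atg_to_tss(probe$positions_atg, probe$tss_offset_atg)
  lin <- zf_to_lin(pos_tss)
  win <- zf_to_lin(spec$window_start_tss):zf_to_lin(spec$window_end_tss)
  if (!all(win %in% lin))
    pk_stop("footprint window not covered by the probe", "invalid_input")

  sizes <- seq_len(probe$probe_len)
  scan_of <- function(s) scan_offset + peak_spacing_scans * (s - 1) +
    curvature * (s - 1)^2
  centers <- scan_of(sizes)
  ladder_centers <- scan_of(ladder_sizes)
  n_scan <- ceiling(max(centers, ladder_centers) + 8 * peak_width_scans)

  set.seed(seed)
  jitter <- if (jitter_sd > 0)
    exp(stats::rnorm(length(sizes), 0, jitter_sd)) else rep(1, length(sizes))
  h_without <- base_height * jitter
  factor <- rep(1, length(sizes))
  factor[lin %in% win] <- spec$attenuation
  hs <- spec$hypersensitive_sites
  if (nrow(hs) > 0) {
    hit <- match(zf_to_lin(hs$position), lin)
    pk_assert(!anyNA(hit), "hypersensitive site outside probe")
    factor[hit] <- factor[hit] * hs$amplification
  }
  h_with <- h_without * factor

  mk <- function(heights, label) {
    smp <- add_peaks(numeric(n_scan), centers, heights, peak_width_scans)
    lad <- add_peaks(numeric(n_scan), ladder_centers,
                     rep(ladder_height, length(ladder_centers)),
                     peak_width_scans)
    if (noise_sd > 0) {
      smp <- smp + stats::rnorm(n_scan, 0, noise_sd)
      lad <- lad + stats::rnorm(n_scan, 0, noise_sd)
    }
    fa_trace(seq_len(n_scan), smp, lad, label)
  }
  list(with = mk(h_with, "with_protein"),
       without = mk(h_without, "without_protein"))
}
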