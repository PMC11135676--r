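#' Differential peak-height profile
#'
#' Given matched peak pairs, sum-normalizes the with-protein and
#' without-protein heights separately over the matched peaks only and
#' subtracts: D = normalized(with) - normalized(without), so that DNase I
#' protection gives negative values and hypersensitivity positive values.
#' Because both operands sum to 1, the profile sums to 0.
#'
#' @param pairs data.frame of matched pairs as returned by
#'   [match_peaks()]`$pairs` (columns `size_bp`, `with_height`,
#'   `without_height`).
#' @param positions optional positions to attach (e.g. promoter
#'   coordinates); defaults to `round(pairs$size_bp)`.  Must be strictly
#'   increasing after ordering by size.
#' @return object of class `differential_profile` with fields `positions`,
#'   `values`, `matched_n`, and the normalized height vectors.
#' @export
differential_profile <- function(pairs, positions = NULL) {
  pk_assert(nrow(pairs) >= 1, "no matched pairs")
  ord <- order(pairs$size_bp)
  pairs <- pairs[ord, , drop = FALSE]
  if (is.null(positions)) positions <- round(pairs$size_bp)
  else positions <- positions[ord]
  pk_assert(all(diff(positions) > 0), "positions must be strictly increasing")
  nw <- normalize_heights(pairs$with_height)
  no <- normalize_heights(pairs$without_height)
  structure(list(positions = positions, values = nw - no,
                 matched_n = nrow(pairs),
                 norm_with = nw, norm_without = no),
            class = "differential_profile")
}

#' Call protected and hypersensitive regions from a differential profile
#'
#' The raw differentials are first standardized to a scale-free score
#' s = matched_n * (D - median(D)): multiplying by the number of matched
#' peaks expresses each differential in units of the uniform per-peak share
#' (so the score does not shrink with probe length), and centring on the
#' median removes the uniform positive offset that sum-normalization places
#' on unprotected positions whenever signal is lost inside a footprint.
#' Maximal runs of at least `min_run` consecutive profile positions with
#' score <= -tau are reported as protected regions; runs with score >= +tau
#' as hypersensitive regions.
#'
#' @param profile a [differential_profile()], with positions in promoter
#'   coordinates.
#' @param tau score threshold; `NULL` (default) uses
#'   `max(0.02, 2 * mad(score))`.
#' @param min_run minimum run length in positions (default 3).
#' @return data.frame with columns `start_tss`, `end_tss`, `kind`
#'   (`"protected"` or `"hypersensitive"`), `mean_differential` (mean raw D
#'   over the run) and `peak_count`; zero rows if nothing is called.
#' @export
call_regions <- function(profile, tau = NULL, min_run = 3) {
  d <- profile$values
  score <- profile$matched_n * (d - stats::median(d))
  if (is.null(tau)) tau <- max(0.02, 2 * stats::mad(score))
  runs_of <- function(flag, kind) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.frame(start_tss = profile$positions[starts[keep]],
               end_tss = profile$positions[ends[keep]],
               kind = kind,
               mean_differential = vapply(which(keep), function(k)
                 mean(d[starts[k]:ends[k]]), numeric(1)),
               peak_count = r$lengths[keep])
  }
  out <- rbind(runs_of(score <= -tau, "protected"),
               runs_of(score >= tau, "hypersensitive"))
  if (is.null(out))
    out <- data.frame(start_tss = integer(0), end_tss = integer(0),
                      kind = character(0), mean_differential = numeric(0),
                      peak_count = integer(0))
  out[order(out$start_tss), , drop = FALSE]
}

#' Run the full footprinting analysis on a trace pair
#'
#' Ladder calibration, peak detection, size assignment, cross-trace peak
#' matching, sum-normalization, differential profile, promoter-coordinate
#' conversion, and region calling.
#'
#' @param with_trace,without_trace [fa_trace()] objects sharing a ladder
#'   configuration.
#' @param probe a [probe_map()].
#' @param ladder_sizes ladder fragment sizes (default [liz500_sizes()]).
#' @param min_height_frac sample peaks below this fraction of the tallest
#'   detected peak are discarded (default 0.01).
#' @param tol_bp size-match tolerance (default 0.5 bp).
#' @param tau,min_run region-calling parameters, see [call_regions()].
#' @return list with `profile` (a [differential_profile()] in promoter
#'   coordinates), `regions` (data.frame from [call_regions()]), and
#'   `calibration` diagnostics for each trace.
#' @export
analyze_footprint <- function(with_trace, without_trace, probe,
                              ladder_sizes = liz500_sizes(),
                              min_height_frac = 0.01, tol_bp = 0.5,
                              tau = NULL, min_run = 3) {
  one <- function(trace) {
    lad <- detect_peaks(trace$ladder_signal, scan = trace$scan)
    if (nrow(lad) > 0)
      lad <- lad[lad$height >= min_height_frac * max(lad$height), ]
    cal <- calibrate_sizes(lad, ladder_sizes)
    pk <- detect_peaks(trace$sample_signal, scan = trace$scan)
    pk <- pk[pk$height >= min_height_frac * max(pk$height), ]
    pk$size_bp <- predict_sizes(cal, pk$scan_pos)
    pk <- pk[round(pk$size_bp) >= 1 & round(pk$size_bp) <= probe$probe_len, ]
    list(peaks = pk, calibration = cal)
  }
  w <- one(with_trace)
  o <- one(without_trace)
  m <- match_peaks(w$peaks, o$peaks, tol_bp = tol_bp)
  pk_assert(nrow(m$pairs) >= 1, "no matched peaks between traces")
  pos <- to_promoter_coords(m$pairs$size_bp, probe)
  ord <- order(pos)
  prof <- differential_profile(m$pairs[ord, , drop = FALSE],
                               positions = pos[ord])
  list(profile = prof,
       regions = call_regions(prof, tau = tau, min_run = min_run),
       calibration = list(with = w$calibration, without = o$calibration),
       unmatched = list(with = m$unmatched_with,
                        without = m$unmatched_without))
}
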