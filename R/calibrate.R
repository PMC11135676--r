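#' Build a scan-to-size calibration from ladder peaks
#'
#' Takes the N tallest peaks detected in the ladder channel (N = number of
#' ladder fragment sizes), assigns the sizes to them in scan order, and
#' builds a monotone piecewise-linear scan-to-bp mapping with linear
#' extrapolation beyond the outermost anchors.
#'
#' @param ladder_peaks data.frame with columns `scan_pos` and `height`
#'   (candidate ladder peaks).
#' @param ladder_sizes fragment sizes in bp, strictly increasing
#'   (default [liz500_sizes()]).
#' @return object of class `size_calibration` with the anchor table and the
#'   interpolation rule identifier.
#' @export
calibrate_sizes <- function(ladder_peaks, ladder_sizes = liz500_sizes()) {
  pk_assert(all(diff(ladder_sizes) > 0),
            "ladder sizes must be strictly increasing")
  n <- length(ladder_sizes)
  if (nrow(ladder_peaks) < n)
    pk_stop(sprintf("found %d ladder peaks for %d ladder sizes",
                    nrow(ladder_peaks), n), "calibration_failure")
  top <- ladder_peaks[order(ladder_peaks$height, decreasing = TRUE), ][1:n, ]
  anchors <- data.frame(scan_pos = sort(top$scan_pos),
                        size_bp = as.numeric(ladder_sizes))
  if (any(diff(anchors$scan_pos) <= 0))
    pk_stop("ladder anchor scans are not strictly increasing",
            "calibration_failure")
  structure(list(anchors = anchors, rule = "piecewise_linear"),
            class = "size_calibration")
}

#' Convert scan positions to fragment sizes
#'
#' Piecewise-linear interpolation between calibration anchors, with linear
#' extrapolation using the slope of the outermost segment on each side.
#'
#' @param calibration a [calibrate_sizes()] result.
#' @param scan_pos scan position(s).
#' @return calibrated size(s) in bp.
#' @export
predict_sizes <- function(calibration, scan_pos) {
  a <- calibration$anchors
  n <- nrow(a)
  out <- stats::approx(a$scan_pos, a$size_bp, xout = scan_pos,
                       rule = 1)$y
  lo <- scan_pos < a$scan_pos[1]
  hi <- scan_pos > a$scan_pos[n]
  if (any(lo)) {
    s <- (a$size_bp[2] - a$size_bp[1]) / (a$scan_pos[2] - a$scan_pos[1])
    out[lo] <- a$size_bp[1] + s * (scan_pos[lo] - a$scan_pos[1])
  }
  if (any(hi)) {
    s <- (a$size_bp[n] - a$size_bp[n - 1]) /
      (a$scan_pos[n] - a$scan_pos[n - 1])
    out[hi] <- a$size_bp[n] + s * (scan_pos[hi] - a$scan_pos[n])
  }
  out
}
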