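#' Detect local-maximum peaks in a signal series
#'
#' Returns interior points strictly greater than both neighbours; a flat
#' plateau flanked by lower values counts once, at its leftmost point.
#' Peaks are filtered by minimum height and by minimum prominence (height
#' above the higher of the two flanking valleys, where each valley is the
#' minimum between the peak and the nearest strictly higher point, or the
#' series end).
#'
#' @param signal numeric series (length >= 3).
#' @param min_height minimum peak height (default 0 = no filter).
#' @param min_prominence minimum prominence (default 0 = no filter).
#' @param scan optional scan indices (defaults to `seq_along(signal)`).
#' @return data.frame with columns `scan_pos` and `height`, sorted by scan;
#'   may be empty.
#' @export
detect_peaks <- function(signal, min_height = 0, min_prominence = 0,
                         scan = seq_along(signal)) {
  n <- length(signal)
  pk_assert(n >= 3, "series too short")
  ## collapse plateaus: runs of equal values, keep run boundaries
  r <- rle(signal)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  is_peak <- logical(m)
  if (m >= 3)
    is_peak[2:(m - 1)] <- v[2:(m - 1)] > v[1:(m - 2)] &
      v[2:(m - 1)] > v[3:m]
  idx <- starts[is_peak]  # leftmost point of each plateau-peak
  if (length(idx) == 0)
    return(data.frame(scan_pos = integer(0), height = numeric(0)))
  h <- signal[idx]
  keep <- h >= min_height
  if (min_prominence > 0) {
    prom <- vapply(idx, function(i) peak_prominence(signal, i), numeric(1))
    keep <- keep & prom >= min_prominence
  }
  data.frame(scan_pos = scan[idx[keep]], height = h[keep])
}

## Prominence of the peak at index i: height minus the higher of the two
## flanking valley minima (valley = stretch to the nearest strictly higher
## point on that side, or the series end).
peak_prominence <- function(signal, i) {
  h <- signal[i]
  left <- signal[seq_len(i - 1)]
  higher <- which(left > h)
  lmin <- min(signal[(if (length(higher)) max(higher) + 1L else 1L):i])
  right <- signal[i:length(signal)]
  higher <- which(right > h)
  rmin <- min(right[1:(if (length(higher)) min(higher) else length(right))])
  h - max(lmin, rmin)
}

#' Sum-normalize peak heights
#'
#' Divides each height by the sum of all heights so the result sums to 1.
#'
#' @param heights positive peak heights (>= 1 value).
#' @return normalized heights summing to 1.
#' @export
normalize_heights <- function(heights) {
  pk_assert(length(heights) >= 1, "no peaks to normalize")
  pk_assert(all(heights > 0), "heights must be positive")
  heights / sum(heights)
}

#' Match peaks between two calibrated traces by fragment size
#'
#' Pairs peaks across the with- and without-protein traces by nearest
#' calibrated size within a tolerance.  Both size lists are sorted and the
#' pairing is the non-crossing matching of maximum cardinality and, among
#' those, minimum total absolute size difference (which for sorted lists and
#' absolute-difference costs is the globally optimal assignment).
#'
#' @param with_peaks,without_peaks data.frames with columns `size_bp` and
#'   `height` (calibrated peaks).
#' @param tol_bp maximum size difference for a match (default 0.5 bp).
#' @return list with `pairs` (data.frame: `size_bp` mean matched size,
#'   `with_height`, `without_height`, `with_size`, `without_size`) and
#'   `unmatched_with`, `unmatched_without` (row indices of unmatched peaks).
#' @export
match_peaks <- function(with_peaks, without_peaks, tol_bp = 0.5) {
  a <- with_peaks[order(with_peaks$size_bp), , drop = FALSE]
  b <- without_peaks[order(without_peaks$size_bp), , drop = FALSE]
  n <- nrow(a); m <- nrow(b)
  ## DP over prefixes: maximize matches, then minimize total |size diff|.
  ## score = matches * BIG - cost, maximized.
  BIG <- (max(tol_bp, 1) * (n + m) + 1) * 1e6
  score <- matrix(0, n + 1, m + 1)
  move <- matrix(0L, n + 1, m + 1)  # 1 = skip a, 2 = skip b, 3 = match
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s1 <- score[i, j + 1]          # skip a[i]
      s2 <- score[i + 1, j]          # skip b[j]
      best <- max(s1, s2)
      mv <- if (s1 >= s2) 1L else 2L
      d <- abs(a$size_bp[i] - b$size_bp[j])
      if (d <= tol_bp) {
        s3 <- score[i, j] + BIG - d
        if (s3 > best) { best <- s3; mv <- 3L }
      }
      score[i + 1, j + 1] <- best
      move[i + 1, j + 1] <- mv
    }
  }
  ## trace back
  i <- n; j <- m
  mi <- integer(0); mj <- integer(0)
  while (i > 0 && j > 0) {
    mv <- move[i + 1, j + 1]
    if (mv == 3L) { mi <- c(i, mi); mj <- c(j, mj); i <- i - 1; j <- j - 1 }
    else if (mv == 1L) i <- i - 1
    else j <- j - 1
  }
  pairs <- data.frame(
    size_bp = (a$size_bp[mi] + b$size_bp[mj]) / 2,
    with_height = a$height[mi], without_height = b$height[mj],
    with_size = a$size_bp[mi], without_size = b$size_bp[mj])
  list(pairs = pairs,
       unmatched_with = setdiff(seq_len(n), mi),
       unmatched_without = setdiff(seq_len(m), mj))
}
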