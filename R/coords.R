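## Zero-free promoter coordinates.
##
## Promoter biology numbers positions ... -2, -1, +1, +2 ... with no zero:
## -1 is immediately adjacent to +1.  All interval arithmetic in this package
## goes through a linearized axis where -1 maps to 0, so ordinary integer
## arithmetic applies, and back.

#' Convert zero-free coordinates to a linear integer axis
#'
#' Maps the zero-free axis (..., -2, -1, +1, +2, ...) onto ordinary integers
#' (..., -1, 0, 1, 2, ...) so that adjacent positions differ by exactly 1.
#'
#' @param x integer vector of zero-free coordinates (no element may be 0).
#' @return integer vector on the linear axis.
#' @export
zf_to_lin <- function(x) {
  pk_assert(all(x != 0), "zero is not a valid zero-free coordinate")
  ifelse(x > 0, x, x + 1L)
}

#' Convert linear integers back to zero-free coordinates
#'
#' Inverse of [zf_to_lin()].
#'
#' @param x integer vector on the linear axis.
#' @return integer vector of zero-free coordinates.
#' @export
lin_to_zf <- function(x) {
  ifelse(x >= 1, x, x - 1L)
}

#' Length of a closed zero-free interval
#'
#' Number of positions in `[from, to]` on the zero-free axis; e.g. the
#' interval -2..+2 holds 4 positions because there is no position 0.
#'
#' @param from,to zero-free coordinates, `from <= to` on the zero-free axis.
#' @return integer count of positions.
#' @export
zf_interval_length <- function(from, to) {
  a <- zf_to_lin(from); b <- zf_to_lin(to)
  pk_assert(all(b >= a), "interval end precedes start")
  as.integer(b - a + 1L)
}

#' Describe a 5'-labeled footprinting probe
#'
#' A probe is a PCR fragment with a fluorescent label on its 5' end; DNase I
#' fragments retain the label, so a fragment of size s ends at the s-th probe
#' position counting from the labeled end.  Coordinates are zero-free,
#' relative to the ATG start codon; the transcription start site (TSS) offset
#' rebases them onto the promoter axis used for reporting.
#'
#' @param label_end_atg zero-free coordinate (rel. ATG) of the labeled 5' end.
#' @param probe_len probe length in bp.
#' @param tss_offset_atg zero-free coordinate of the TSS relative to the ATG.
#'   Must be supplied by the user for real data; synthetic presets fix it.
#' @return an object of class `probe_map`.
#' @export
probe_map <- function(label_end_atg, probe_len, tss_offset_atg) {
  pk_assert(probe_len >= 1, "probe_len must be >= 1")
  pk_assert(label_end_atg != 0 && tss_offset_atg != 0,
            "coordinates are zero-free; 0 is invalid")
  positions_atg <- lin_to_zf(zf_to_lin(label_end_atg) + seq_len(probe_len) - 1L)
  structure(list(label_end_atg = as.integer(label_end_atg),
                 probe_len = as.integer(probe_len),
                 tss_offset_atg = as.integer(tss_offset_atg),
                 positions_atg = as.integer(positions_atg),
                 deleted_tss = integer(0)),
            class = "probe_map")
}

## Rebase a zero-free ATG coordinate onto the zero-free TSS axis.
atg_to_tss <- function(pos_atg, tss_offset_atg) {
  d <- zf_to_lin(pos_atg) - zf_to_lin(tss_offset_atg)
  ifelse(d >= 0, d + 1L, d)  # the TSS itself is +1
}

#' Map a calibrated fragment size to a promoter position
#'
#' Fragment size s (bp) corresponds to the s-th probe position from the
#' labeled 5' end; the position is reported relative to the TSS on the
#' zero-free axis.  For deletion probes the mapping skips the deleted
#' coordinates.
#'
#' @param size_bp calibrated fragment size(s); rounded to the nearest bp.
#' @param probe a [probe_map()].
#' @return integer position(s) relative to the TSS (zero-free).
#' @export
to_promoter_coords <- function(size_bp, probe) {
  idx <- as.integer(round(size_bp))
  if (any(idx < 1L | idx > probe$probe_len))
    pk_stop(sprintf("fragment size outside probe (1..%d bp)", probe$probe_len),
            "out_of_range")
  atg_to_tss(probe$positions_atg[idx], probe$tss_offset_atg)
}

#' Construct a deletion derivative of a probe
#'
#' Removes the closed zero-free interval `[del_start, del_end]` (coordinates
#' relative to the TSS) from the probe; positions downstream of the gap keep
#' their original promoter coordinates, so the size-to-position mapping skips
#' the deleted stretch.
#'
#' @param probe a [probe_map()].
#' @param del_start,del_end zero-free TSS-relative coordinates of the
#'   deletion, `del_start <= del_end`.
#' @return a `probe_map` with reduced `probe_len` and a record of the deleted
#'   coordinates in `$deleted_tss`.
#' @export
build_deletion_probe <- function(probe, del_start, del_end) {
  pos_tss <- atg_to_tss(probe$positions_atg, probe$tss_offset_atg)
  a <- zf_to_lin(del_start); b <- zf_to_lin(del_end)
  pk_assert(b >= a, "deletion end precedes start")
  lin <- zf_to_lin(pos_tss)
  drop <- lin >= a & lin <= b
  if (!any(drop) || sum(drop) != (b - a + 1L))
    pk_stop("deletion interval not fully inside probe", "invalid_input")
  out <- probe
  out$positions_atg <- probe$positions_atg[!drop]
  out$probe_len <- length(out$positions_atg)
  out$deleted_tss <- pos_tss[drop]
  out
}
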