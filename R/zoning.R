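#' Segment a maneuver into the five analysis zones
#'
#' The flow-volume curve is divided into five (possibly overlapping) zones on
#' a common sample-index base:
#' \describe{
#'   \item{Z1}{ascent: expiration onset up to and including the PEF sample.}
#'   \item{Z2}{peak region: the contiguous band around PEF where flow is at
#'     least `cfg$z2_fraction` of PEF.}
#'   \item{Z3}{descent: from the right edge of Z2 to the start of Z4.}
#'   \item{Z4}{end of test: the final `max(1 s, cfg$z4_window)` of the record.}
#'   \item{Z5}{the whole curve.}
#' }
#' Onset is the first sample whose (smoothed) flow reaches
#' `cfg$onset_fraction` of PEF. Each zone is a half-open index interval
#' `[start, end)` in 1-based sample indices.
#'
#' @param mnv A [maneuver()].
#' @param indices Output of [compute_indices()] for `mnv`.
#' @param cfg A [default_config()].
#' @return A list of class `zone_segmentation` with elements `z1`..`z5`,
#'   each `c(start, end)`, plus `onset` and `pef_idx`.
#' @export
segment_zones <- function(mnv, indices, cfg = default_config()) {
  n <- length(mnv$time)
  if (indices$PEF <= 0) stop_degenerate("PEF must be positive")
  w4 <- max(1.0, cfg$z4_window)
  if (mnv$time[n] - mnv$time[1] < w4) {
    stop_degenerate("record shorter than the end-of-test window")
  }
  fs <- smooth_signal(mnv$flow, mnv$time, cfg$smoothing_window)
  pef_idx <- which.max(mnv$flow)
  onset <- which(fs >= cfg$onset_fraction * indices$PEF)[1]
  if (is.na(onset) || onset > pef_idx) onset <- 1L

  in_band <- fs >= cfg$z2_fraction * indices$PEF
  lo <- pef_idx
  while (lo > 1L && in_band[lo - 1L]) lo <- lo - 1L
  hi <- pef_idx
  while (hi < n && in_band[hi + 1L]) hi <- hi + 1L

  z4_start <- which(mnv$time >= mnv$time[n] - w4)[1]
  z3_start <- min(hi + 1L, n)
  z3_end <- max(z3_start, z4_start)

  structure(
    list(z1 = c(onset, pef_idx + 1L),
         z2 = c(lo, hi + 1L),
         z3 = c(z3_start, z3_end),
         z4 = c(z4_start, n + 1L),
         z5 = c(1L, n + 1L),
         onset = onset, pef_idx = pef_idx),
    class = "zone_segmentation")
}

#' @export
print.zone_segmentation <- function(x, ...) {
  cat("<zone_segmentation> [start, end) sample indices\n")
  for (z in c("z1", "z2", "z3", "z4", "z5")) {
    cat(sprintf("  %s: [%d, %d)\n", z, x[[z]][1], x[[z]][2]))
  }
  invisible(x)
}

zone_idx <- function(seg, zone) {
  iv <- seg[[zone]]
  if (iv[2] <= iv[1]) integer(0) else seq.int(iv[1], iv[2] - 1L)
}
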