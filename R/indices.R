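#' Back-extrapolated time origin of a maneuver
#'
#' The ATS/ERS time origin for timed indices: the tangent to the volume-time
#' curve at its point of maximum slope is extended down to zero volume, and
#' the crossing time is returned. The slope estimate uses the flow signal
#' (dV/dt) after local-quadratic smoothing over `cfg$smoothing_window`.
#'
#' @param mnv A [maneuver()].
#' @param cfg A [default_config()].
#' @return The crossing time `T_zero` (s), on the maneuver's own time axis.
#' @export
compute_t_zero <- function(mnv, cfg = default_config()) {
  if (max(mnv$flow) <= 0) stop_degenerate("flow is never positive; no expiration")
  slope <- smooth_signal(mnv$flow, mnv$time, cfg$smoothing_window)
  i <- which.max(slope)          # earliest maximum-slope sample
  mnv$time[i] - mnv$volume[i] / slope[i]
}

interp_volume <- function(mnv, t) {
  approx(mnv$time, mnv$volume, t, rule = 2)$y
}

#' Classical spirometric indices of one maneuver
#'
#' Computes, on the back-extrapolated time origin `T_zero`:
#' \describe{
#'   \item{FVC}{forced vital capacity, the maximum expired volume (L).}
#'   \item{FEV1}{volume expired between `T_zero` and `T_zero` + 1 s (L);
#'     `NA` with `fev1_reason = "record_too_short"` if the record ends
#'     before `T_zero` + 1 s.}
#'   \item{PEF, PEFT}{peak expiratory flow (L/s) and its time after
#'     `T_zero` (s).}
#'   \item{BEV}{back-extrapolated volume: the recorded volume at
#'     `t = T_zero`, linearly interpolated (L); measures a hesitant start.}
#'   \item{EOTV}{end-of-test volume: max minus min volume over the final
#'     `cfg$eotv_window` seconds (L); small values indicate a plateau.}
#'   \item{Tex}{time from `T_zero` until the volume accumulated over the
#'     trailing `cfg$eotv_window` first falls below `cfg$eotv_threshold`,
#'     or to the end of exhalation (s).}
#'   \item{FET100}{time from `T_zero` to the first sample at which the
#'     volume-time curve reaches FVC (s).}
#' }
#'
#' @inheritParams compute_t_zero
#' @return A list of class `spiro_indices`.
#' @export
compute_indices <- function(mnv, cfg = default_config()) {
  t_zero <- compute_t_zero(mnv, cfg)
  t_end <- mnv$time[length(mnv$time)]

  fvc_idx <- which.max(mnv$volume)   # earliest sample reaching max volume
  fvc <- mnv$volume[fvc_idx]
  pef_idx <- which.max(mnv$flow)
  pef <- mnv$flow[pef_idx]

  bev <- max(0, approx(mnv$time, mnv$volume, t_zero, rule = 2)$y)

  fev1 <- NA_real_
  fev1_reason <- NULL
  eotv <- NA_real_
  eotv_reason <- NULL
  if (t_end < t_zero + 1) {
    fev1_reason <- "record_too_short"
  } else {
    fev1 <- interp_volume(mnv, t_zero + 1) - bev
    fev1 <- min(max(fev1, 0), fvc)
  }
  if (t_end - mnv$time[1] < cfg$eotv_window) {
    eotv_reason <- "record_too_short"
  } else {
    in_win <- mnv$time >= t_end - cfg$eotv_window
    eotv <- max(mnv$volume[in_win]) - min(mnv$volume[in_win])
  }

  # Tex: trailing-anchored sliding window; first time the volume expired in
  # the previous eotv_window drops below eotv_threshold
  tex <- t_end - t_zero
  cand <- which(mnv$time >= mnv$time[1] + cfg$eotv_window)
  if (length(cand)) {
    dv <- mnv$volume[cand] - interp_volume(mnv, mnv$time[cand] - cfg$eotv_window)
    hit <- which(dv < cfg$eotv_threshold)
    if (length(hit)) tex <- mnv$time[cand[hit[1]]] - t_zero
  }

  structure(
    list(FVC = fvc, FEV1 = fev1, PEF = pef,
         PEFT = mnv$time[pef_idx] - t_zero,
         T_zero = t_zero, BEV = bev, EOTV = eotv,
         Tex = tex, FET100 = mnv$time[fvc_idx] - t_zero,
         fev1_reason = fev1_reason, eotv_reason = eotv_reason),
    class = "spiro_indices")
}

#' @export
print.spiro_indices <- function(x, ...) {
  cat("<spiro_indices>\n")
  for (k in c("FVC", "FEV1", "PEF", "PEFT", "T_zero", "BEV", "EOTV", "Tex",
              "FET100")) {
    cat(sprintf("  %-7s %8.4f\n", k, x[[k]]))
  }
  invisible(x)
}
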