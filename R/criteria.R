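#' Zone Z1 criteria: regularity of the ascent to peak flow
#'
#' Evaluates three shape criteria on the rising limb of the flow-volume
#' curve (onset to PEF):
#' \describe{
#'   \item{C1}{irregular concavity/convexity: the second derivative of flow
#'     with respect to volume (on a uniform volume grid, normalized by PEF
#'     and the Z1 volume span) changes sign more than `c1_signflip_max`
#'     times with amplitude above `c1_amp_floor`.}
#'   \item{C2a}{irregular slope: the standard deviation of the
#'     high-frequency flow residual (raw minus a 70-ms local-quadratic
#'     smooth) over Z1, normalized by PEF, exceeds `c2a_resid_max`. A
#'     clean rise leaves only sensor noise in this residual, so ripple
#'     riding on the ascent stands out; the first-derivative coefficient
#'     of variation is reported alongside but is too
#'     discretization-sensitive on a 0.1-s window to gate on.}
#'   \item{C2b}{curvature excursion: the maximum absolute normalized second
#'     derivative exceeds `c2b_excursion_max`.}
#' }
#' These are derivative-statistic surrogates for ascent-regularity metrics;
#' their exact published forms are proprietary, so the shapes measured here
#' are this package's own (documented) constructions.
#'
#' @param mnv A [maneuver()].
#' @param seg A [segment_zones()] result.
#' @param indices A [compute_indices()] result.
#' @param cfg A [default_config()].
#' @return List of `criterion_result` objects (C1, C2a, C2b).
#' @export
evaluate_z1 <- function(mnv, seg, indices, cfg = default_config()) {
  idx <- zone_idx(seg, "z1")
  if (length(idx) < 5L) {
    return(lapply(c("C1", "C2a", "C2b"), not_applicable,
                  reason = "Z1 shorter than 5 samples"))
  }
  pef <- indices$PEF

  # normalized curvature on the uniform-volume grid
  g <- fv_grid(mnv, idx)
  if (is.null(g)) {
    c1 <- not_applicable("C1", "Z1 volume span too small")
    c2b <- not_applicable("C2b", "Z1 volume span too small")
  } else {
    span <- g$v[length(g$v)] - g$v[1]
    fn <- g$f / pef
    vn <- (g$v - g$v[1]) / span
    d2 <- differentiate(fn, vn, 2L)
    # interior only: one-sided endpoint estimates are copies, not data
    d2 <- d2[2:(length(d2) - 1L)]
    flips <- count_sign_changes(d2, floor = cfg$c1_amp_floor * max(abs(d2), 1e-12))
    c1 <- criterion_result("C1",
      metrics = list(signflips = flips),
      thresholds = list(c1_signflip_max = cfg$c1_signflip_max),
      outcome = verdict(flips > cfg$c1_signflip_max))
    exc <- max(abs(d2))
    c2b <- criterion_result("C2b",
      metrics = list(curvature_excursion = exc),
      thresholds = list(c2b_excursion_max = cfg$c2b_excursion_max),
      outcome = verdict(exc > cfg$c2b_excursion_max))
  }

  dfdt <- differentiate(mnv$flow, mnv$time, 1L)[idx]
  cv <- if (abs(mean(dfdt)) < 1e-12) Inf else sd(dfdt) / abs(mean(dfdt))
  # trend removal over c2a_trend_window (longer than the derivative
  # smoothing window, so ascent-band ripple lands in the residual); the
  # slope kink at the PEF corner leaks into the residual of the last
  # half-window of samples, so they are excluded from the noise estimate
  fsm <- smooth_signal(mnv$flow, mnv$time, cfg$c2a_trend_window)
  ridx <- idx[seq_len(max(3L, length(idx) - 2L))]
  resid_sd <- sd((mnv$flow - fsm)[ridx]) / pef
  c2a <- criterion_result("C2a",
    metrics = list(slope_cv = cv, resid_sd = resid_sd),
    thresholds = list(c2a_resid_max = cfg$c2a_resid_max),
    outcome = verdict(resid_sd > cfg$c2a_resid_max))

  list(c1, c2a, c2b)
}

#' Zone Z2 criteria: peak timing and peak shape
#'
#' \describe{
#'   \item{C3}{peak too late: `PEFT > peft_max`.}
#'   \item{C4}{peak too early: `PEFT < peft_min`.}
#'   \item{C5a/C5b}{flat peak: the time spent with flow at or above
#'     `flat_peak_ratio * PEF` exceeds `flat_peak_width_max`. C5a measures
#'     the contiguous band containing PEF, C5b the total time in the band.}
#'   \item{C5c}{bimodal peak: at least two local flow maxima inside Z2 with
#'     prominence at least `bimodal_prominence * PEF`.}
#'   \item{C6}{slow peak: the height-to-size ratio `PEF / FVC` falls below
#'     `c6_threshold` (interpreting the "too low peak value" check as a
#'     PEF-to-FVC ratio so it is size-independent).}
#' }
#'
#' @inheritParams evaluate_z1
#' @return List of `criterion_result` objects (C3, C4, C5a, C5b, C5c, C6).
#' @export
evaluate_z2 <- function(mnv, seg, indices, cfg = default_config()) {
  pef <- indices$PEF
  dt <- 1 / mnv$sample_rate
  fs <- smooth_signal(mnv$flow, mnv$time, cfg$smoothing_window)

  c3 <- criterion_result("C3",
    metrics = list(PEFT = indices$PEFT),
    thresholds = list(peft_max = cfg$peft_max),
    outcome = verdict(indices$PEFT > cfg$peft_max))
  c4 <- criterion_result("C4",
    metrics = list(PEFT = indices$PEFT),
    thresholds = list(peft_min = cfg$peft_min),
    outcome = verdict(indices$PEFT < cfg$peft_min))

  band <- fs >= cfg$flat_peak_ratio * pef
  # contiguous band through the PEF sample
  pk <- seg$pef_idx
  lo <- pk
  while (lo > 1L && band[lo - 1L]) lo <- lo - 1L
  hi <- pk
  while (hi < length(band) && band[hi + 1L]) hi <- hi + 1L
  width_contig <- (hi - lo) * dt
  width_total <- sum(band) * dt
  c5a <- criterion_result("C5a",
    metrics = list(flat_band_width = width_contig),
    thresholds = list(flat_peak_width_max = cfg$flat_peak_width_max,
                      flat_peak_ratio = cfg$flat_peak_ratio),
    outcome = verdict(width_contig > cfg$flat_peak_width_max))
  c5b <- criterion_result("C5b",
    metrics = list(flat_total_width = width_total),
    thresholds = list(flat_peak_width_max = cfg$flat_peak_width_max,
                      flat_peak_ratio = cfg$flat_peak_ratio),
    outcome = verdict(width_total > cfg$flat_peak_width_max))

  # prominence is computed on the whole curve (a mode's descent continues
  # below the band), then modes are counted inside the hull of the peak
  # band: a genuinely bimodal peak breaks the band's contiguity, so the
  # contiguous Z2 interval alone cannot contain both modes
  band_idx <- which(fs >= cfg$z2_fraction * pef)
  z2 <- if (length(band_idx)) range(band_idx) else seg$z2
  pks <- find_prominent_peaks(fs, cfg$bimodal_prominence * pef)
  pks <- pks[pks >= z2[1] & pks <= z2[2]]
  c5c <- criterion_result("C5c",
    metrics = list(n_peaks_z2 = length(pks)),
    thresholds = list(bimodal_prominence = cfg$bimodal_prominence),
    outcome = verdict(length(pks) >= 2L))

  ratio <- pef / indices$FVC
  c6 <- criterion_result("C6",
    metrics = list(pef_fvc_ratio = ratio),
    thresholds = list(c6_threshold = cfg$c6_threshold),
    outcome = verdict(ratio < cfg$c6_threshold))

  list(c3, c4, c5a, c5b, c5c, c6)
}

#' Zone Z3 criteria: regularity of the descent from peak flow
#'
#' All four criteria work on the slope of the flow-volume curve,
#' `dF/dV = (dF/dt) / F`, evaluated where flow is above
#' `c7_flow_floor * PEF` (the ratio is unstable at near-zero flow):
#' \describe{
#'   \item{C7a}{maximum `|dF/dV|` over Z3 exceeds `c7_slope_max`. A smooth
#'     exponential-like descent has nearly constant `dF/dV`; coughs and
#'     abrupt flow losses produce sharp spikes.}
#'   \item{C7b}{variance of `dF/dV` over Z3 exceeds `c7_slope_var_max`.}
#'   \item{C7c}{the same variance inside any sliding volume window of width
#'     `c7_segment_width` exceeds `c7_segment_var_max`.}
#'   \item{C7d}{irregular slope: the number of `dF/dV` sign changes,
#'     weighted by the mean absolute deviation of the curve from the
#'     straight chord across Z3 (normalized by PEF), exceeds
#'     `c7_signflip_max`.}
#' }
#'
#' @inheritParams evaluate_z1
#' @return List of `criterion_result` objects (C7a, C7b, C7c, C7d).
#' @export
evaluate_z3 <- function(mnv, seg, indices, cfg = default_config()) {
  idx <- zone_idx(seg, "z3")
  if (length(idx) < 5L) {
    return(lapply(c("C7a", "C7b", "C7c", "C7d"), not_applicable,
                  reason = "Z3 shorter than 5 samples"))
  }
  sl <- fv_slope(mnv, idx, cfg, indices$PEF)
  if (is.null(sl)) {
    return(lapply(c("C7a", "C7b", "C7c", "C7d"), not_applicable,
                  reason = "too little usable flow in Z3"))
  }
  smax <- max(abs(sl$slope))
  c7a <- criterion_result("C7a",
    metrics = list(max_abs_slope = smax),
    thresholds = list(c7_slope_max = cfg$c7_slope_max),
    outcome = verdict(smax > cfg$c7_slope_max))

  svar <- var(sl$slope)
  c7b <- criterion_result("C7b",
    metrics = list(slope_var = svar),
    thresholds = list(c7_slope_var_max = cfg$c7_slope_var_max),
    outcome = verdict(svar > cfg$c7_slope_var_max))

  # sliding volume windows
  wvar <- 0
  if (length(sl$volume) >= 5L) {
    v0 <- sl$volume
    for (i in seq_along(v0)) {
      inw <- which(v0 >= v0[i] & v0 <= v0[i] + cfg$c7_segment_width)
      if (length(inw) >= 5L) wvar <- max(wvar, var(sl$slope[inw]))
    }
  }
  c7c <- criterion_result("C7c",
    metrics = list(max_window_var = wvar),
    thresholds = list(c7_segment_var_max = cfg$c7_segment_var_max,
                      c7_segment_width = cfg$c7_segment_width),
    outcome = verdict(wvar > cfg$c7_segment_var_max))

  # chord-weighted sign-change score
  i1 <- idx[1]
  i2 <- idx[length(idx)]
  v <- mnv$volume[idx]
  f <- mnv$flow[idx]
  denom <- mnv$volume[i2] - mnv$volume[i1]
  chord <- if (abs(denom) < 1e-9) {
    rep(mnv$flow[i1], length(idx))
  } else {
    mnv$flow[i1] + (mnv$flow[i2] - mnv$flow[i1]) * (v - mnv$volume[i1]) / denom
  }
  dev <- mean(abs(f - chord)) / indices$PEF
  flips <- count_sign_changes(sl$slope)
  score <- flips * dev
  c7d <- criterion_result("C7d",
    metrics = list(signflips = flips, chord_dev = dev, score = score),
    thresholds = list(c7_signflip_max = cfg$c7_signflip_max),
    outcome = verdict(score > cfg$c7_signflip_max))

  list(c7a, c7b, c7c, c7d)
}

#' Zone Z4 criteria: start and end-of-test quality
#'
#' The traditional back-extrapolation and plateau rules plus their
#' refinements:
#' \describe{
#'   \item{C8}{hesitant start: `BEV > max(bev_abs, bev_frac * FVC)`
#'     (defaults 0.15 L and 5% of FVC; a maneuver is acceptable when BEV
#'     is within either allowance).}
#'   \item{C9}{no plateau: `EOTV >= eotv_threshold` over the final
#'     `eotv_window` (defaults 0.025 L, 1 s).}
#'   \item{C10a}{both end-of-test conditions missed: C9's test fails and
#'     `Tex < fet_min`.}
#'   \item{C10b}{EOTV over the alternative window `c10_window2`, applied
#'     when `Tex >= fet_min`, against `eotv_threshold`.}
#'   \item{C10c}{standard EOTV against the alternative threshold
#'     `c10_threshold2`, when `Tex >= fet_min`.}
#'   \item{C10d}{EOTV against a Tex-indexed threshold curve
#'     `thr(Tex) = eotv_threshold * (1 + c10_eotv_tex_slope *
#'     max(0, fet_min - Tex))` and the traditional threshold; fails only if
#'     both are exceeded.}
#'   \item{C10e}{reports `EOTV / thr(Tex)` and fails above 1.}
#'   \item{C11}{end-of-test oscillation: the first derivative of the
#'     flow-time curve over Z4 changes sign at least `c11_signflip_max`
#'     times with flow swings of at least `c11_osc_amplitude` between
#'     successive extrema.}
#' }
#'
#' @inheritParams evaluate_z1
#' @return List of `criterion_result` objects (C8, C9, C10a-C10e, C11).
#' @export
evaluate_z4 <- function(mnv, seg, indices, cfg = default_config()) {
  res <- list()
  bev_thr <- max(cfg$bev_abs, cfg$bev_frac * indices$FVC)
  res$c8 <- criterion_result("C8",
    metrics = list(BEV = indices$BEV),
    thresholds = list(bev_abs = cfg$bev_abs, bev_frac = cfg$bev_frac,
                      effective = bev_thr),
    outcome = verdict(indices$BEV > bev_thr))

  t_end <- mnv$time[length(mnv$time)]
  if (t_end < indices$T_zero + 1 || is.na(indices$EOTV)) {
    for (id in c("C9", "C10a", "C10b", "C10c", "C10d", "C10e")) {
      res[[id]] <- not_applicable(id, "record shorter than 1 s after T_zero")
    }
  } else {
    eotv <- indices$EOTV
    tex <- indices$Tex
    c9_fail <- eotv >= cfg$eotv_threshold
    res$c9 <- criterion_result("C9",
      metrics = list(EOTV = eotv),
      thresholds = list(eotv_threshold = cfg$eotv_threshold,
                        eotv_window = cfg$eotv_window),
      outcome = verdict(c9_fail))

    res$c10a <- criterion_result("C10a",
      metrics = list(EOTV = eotv, Tex = tex),
      thresholds = list(eotv_threshold = cfg$eotv_threshold,
                        fet_min = cfg$fet_min),
      outcome = verdict(c9_fail && tex < cfg$fet_min))

    in_w2 <- mnv$time >= t_end - cfg$c10_window2
    eotv2 <- max(mnv$volume[in_w2]) - min(mnv$volume[in_w2])
    res$c10b <- criterion_result("C10b",
      metrics = list(EOTV_w2 = eotv2, Tex = tex),
      thresholds = list(c10_window2 = cfg$c10_window2,
                        eotv_threshold = cfg$eotv_threshold),
      outcome = verdict(tex >= cfg$fet_min && eotv2 >= cfg$eotv_threshold))

    res$c10c <- criterion_result("C10c",
      metrics = list(EOTV = eotv, Tex = tex),
      thresholds = list(c10_threshold2 = cfg$c10_threshold2),
      outcome = verdict(tex >= cfg$fet_min && eotv >= cfg$c10_threshold2))

    thr_tex <- cfg$eotv_threshold *
      (1 + cfg$c10_eotv_tex_slope * max(0, cfg$fet_min - tex))
    res$c10d <- criterion_result("C10d",
      metrics = list(EOTV = eotv, thr_tex = thr_tex),
      thresholds = list(eotv_threshold = cfg$eotv_threshold,
                        c10_eotv_tex_slope = cfg$c10_eotv_tex_slope),
      outcome = verdict(eotv > thr_tex && eotv > cfg$eotv_threshold))

    res$c10e <- criterion_result("C10e",
      metrics = list(eotv_ratio = eotv / thr_tex),
      thresholds = list(limit = 1),
      outcome = verdict(eotv / thr_tex > 1))
  }

  idx <- zone_idx(seg, "z4")
  fs <- smooth_signal(mnv$flow, mnv$time, cfg$smoothing_window)[idx]
  d <- differentiate(fs, mnv$time[idx], 1L)
  # extrema of the smoothed flow inside Z4, amplitude = swing between them
  s <- sign(d)
  s[s == 0] <- 1
  turns <- which(diff(s) != 0)
  nflips <- 0L
  max_swing <- 0
  if (length(turns) >= 1L) {
    ext <- fs[c(1L, turns + 1L, length(fs))]
    swings <- abs(diff(ext))
    nflips <- sum(swings >= cfg$c11_osc_amplitude)
    max_swing <- max(swings)
  }
  res$c11 <- criterion_result("C11",
    metrics = list(oscillations = nflips, max_swing = max_swing),
    thresholds = list(c11_signflip_max = cfg$c11_signflip_max,
                      c11_osc_amplitude = cfg$c11_osc_amplitude),
    outcome = verdict(nflips >= cfg$c11_signflip_max))

  unname(res)
}

#' Zone Z5 criteria: the whole curve has a single peak
#'
#' \describe{
#'   \item{C12a}{multiple peaks anywhere (typically a cough): two or more
#'     local flow maxima with prominence at least `c12_prominence * PEF`.}
#'   \item{C12b}{the same test restricted to samples whose expired volume
#'     lies within `c12_fev1_band` of the FEV1 point (volume expired at
#'     `T_zero` + 1 s).}
#' }
#'
#' @inheritParams evaluate_z1
#' @return List of `criterion_result` objects (C12a, C12b).
#' @export
evaluate_z5 <- function(mnv, seg, indices, cfg = default_config()) {
  fs <- smooth_signal(mnv$flow, mnv$time, cfg$smoothing_window)
  pks <- find_prominent_peaks(fs, cfg$c12_prominence * indices$PEF)
  c12a <- criterion_result("C12a",
    metrics = list(n_peaks = length(pks)),
    thresholds = list(c12_prominence = cfg$c12_prominence),
    outcome = verdict(length(pks) >= 2L))

  if (is.na(indices$FEV1)) {
    c12b <- not_applicable("C12b", "FEV1 unavailable")
  } else {
    v_fev1 <- indices$BEV + indices$FEV1
    # secondary peaks: every prominent local maximum except the tallest
    secondary <- if (length(pks) >= 2L) pks[-which.max(fs[pks])] else integer(0)
    near <- abs(mnv$volume[secondary] - v_fev1) <= cfg$c12_fev1_band
    c12b <- criterion_result("C12b",
      metrics = list(n_peaks_near_fev1 = sum(near)),
      thresholds = list(c12_fev1_band = cfg$c12_fev1_band,
                        c12_prominence = cfg$c12_prominence),
      outcome = verdict(sum(near) >= 1L))
  }
  list(c12a, c12b)
}

#' Forced-expiratory-time criterion
#'
#' Fails when `FET100 < fet_min` (default 6 s, the adult rule). The boundary
#' is inclusive: exactly `fet_min` passes.
#'
#' @param indices A [compute_indices()] result.
#' @param cfg A [default_config()].
#' @return A `criterion_result` with id `FET`.
#' @export
evaluate_fet <- function(indices, cfg = default_config()) {
  criterion_result("FET",
    metrics = list(FET100 = indices$FET100),
    thresholds = list(fet_min = cfg$fet_min),
    outcome = verdict(indices$FET100 < cfg$fet_min))
}

#' Session repeatability criterion
#'
#' Passes when at least three maneuvers in the session are individually
#' acceptable and some pair of acceptable maneuvers agrees in both FVC and
#' FEV1 to within `repeatability_delta` (default 0.15 L, strict).
#'
#' @param session_indices List of [compute_indices()] results, one per
#'   maneuver in the session.
#' @param acceptable Logical vector flagging which maneuvers are
#'   individually acceptable; defaults to all of them.
#' @param cfg A [default_config()].
#' @return A `criterion_result` with id `REP`, reporting the best pair's
#'   FVC and FEV1 differences.
#' @export
evaluate_repeatability <- function(session_indices, acceptable = NULL,
                                   cfg = default_config()) {
  if (!length(session_indices)) stop_input("need at least one maneuver")
  if (is.null(acceptable)) acceptable <- rep(TRUE, length(session_indices))
  ok <- which(acceptable)
  if (length(ok) < 3L) {
    return(criterion_result("REP",
      metrics = list(n_acceptable = length(ok)),
      thresholds = list(repeatability_delta = cfg$repeatability_delta),
      outcome = "fail", reason = "insufficient maneuvers"))
  }
  fvc <- vapply(session_indices[ok], `[[`, numeric(1), "FVC")
  fev1 <- vapply(session_indices[ok], `[[`, numeric(1), "FEV1")
  best <- c(Inf, Inf)
  best_pair <- c(NA_integer_, NA_integer_)
  for (a in seq_along(ok)[-length(ok)]) {
    for (b in seq.int(a + 1L, length(ok))) {
      d <- c(abs(fvc[a] - fvc[b]), abs(fev1[a] - fev1[b]))
      if (max(d) < max(best)) {
        best <- d
        best_pair <- ok[c(a, b)]
      }
    }
  }
  pass <- all(is.finite(best)) && all(best < cfg$repeatability_delta)
  criterion_result("REP",
    metrics = list(n_acceptable = length(ok),
                   best_dFVC = best[1], best_dFEV1 = best[2],
                   pair_i = best_pair[1], pair_j = best_pair[2]),
    thresholds = list(repeatability_delta = cfg$repeatability_delta),
    outcome = verdict(!pass))
}

#' Evaluate the full criterion battery on one maneuver
#'
#' Convenience wrapper: computes indices and zones if not supplied, then
#' runs [evaluate_z1()] through [evaluate_z5()] and [evaluate_fet()].
#'
#' @inheritParams evaluate_z1
#' @return List of `criterion_result` objects covering C1-C12b and FET,
#'   each criterion id exactly once.
#' @export
evaluate_criteria <- function(mnv, cfg = default_config(),
                              indices = NULL, seg = NULL) {
  if (is.null(indices)) indices <- compute_indices(mnv, cfg)
  if (is.null(seg)) seg <- segment_zones(mnv, indices, cfg)
  c(evaluate_z1(mnv, seg, indices, cfg),
    evaluate_z2(mnv, seg, indices, cfg),
    evaluate_z3(mnv, seg, indices, cfg),
    evaluate_z4(mnv, seg, indices, cfg),
    evaluate_z5(mnv, seg, indices, cfg),
    list(evaluate_fet(indices, cfg)))
}
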