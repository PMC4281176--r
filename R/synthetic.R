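DEFECT_KINDS <- c("delayed_start", "cough", "bimodal_peak", "flat_peak",
                  "slow_peak", "early_termination", "end_oscillation",
                  "irregular_ascent", "irregular_descent")

#' Criterion designated to detect each defect kind
#'
#' @return Named character vector mapping defect kind to the criterion id
#'   expected to fail when the defect is injected at high severity.
#' @export
designated_criterion <- function() {
  c(delayed_start = "C8", cough = "C12a", bimodal_peak = "C5c",
    flat_peak = "C5a", slow_peak = "C3", early_termination = "FET",
    end_oscillation = "C11", irregular_ascent = "C2a",
    irregular_descent = "C7b")
}

#' Generate a clean synthetic forced-expiration maneuver
#'
#' The flow waveform is a quarter-sine rise to PEF over `rise_time`
#' followed by a two-compartment exponential descent: a fast compartment
#' whose decay constant is solved (by root finding on the discretely
#' integrated volume, tolerance 1e-4 L) so the total expired volume equals
#' `fvc` at `duration`, plus a small slow compartment (decay constant a
#' third of the exhalation, sized to leave about 8 mL/s of flow at the end
#' of the record). The slow tail mimics the long near-plateau emptying of a
#' complete real exhalation: volume keeps rising measurably to the last
#' sample, while the end-of-test volume stays well below the 25-mL plateau
#' allowance. Additive white noise of standard deviation `noise_sd` is
#' applied to the flow, and volume is obtained by trapezoidal integration.
#' The shape is this package's own idealization of a technically good
#' maneuver: a fast single-inflection rise, a monotone convex descent, and
#' a flat end-of-test plateau.
#'
#' @param fvc Forced vital capacity to produce (L).
#' @param pef Peak expiratory flow (L/s).
#' @param rise_time Time from onset to PEF (s).
#' @param duration Total exhalation duration (s). The default 10 s leaves a
#'   clear plateau beyond the 6-s adult minimum expiratory time.
#' @param sample_rate Sampling rate (Hz).
#' @param noise_sd Flow noise standard deviation (L/s).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   state. A fixed seed gives bit-identical output.
#' @param tau Optional fixed descent decay constant (s); when supplied the
#'   FVC constraint is not enforced.
#' @param plateau_flow Residual flow (L/s) left at the last sample by the
#'   slow compartment; 0 gives a fully flat plateau (single-compartment
#'   descent).
#' @return A [maneuver()] whose `meta` records the generating parameters.
#' @export
generate_clean <- function(fvc, pef, rise_time, duration = 10,
                           sample_rate = 100, noise_sd = 0.02,
                           seed = NULL, tau = NULL, plateau_flow = 0.008) {
  if (any(c(fvc, pef, rise_time, duration, sample_rate) <= 0) ||
      noise_sd < 0 || plateau_flow < 0) {
    stop_input("all clean-maneuver parameters must be positive")
  }
  if (rise_time >= duration) stop_input("rise_time must be below duration")
  tt <- seq(0, duration, by = 1 / sample_rate)
  # slow compartment: decay over a third of the exhalation, amplitude set
  # so roughly 8 mL/s of flow remains at the last sample
  tau_slow <- (duration - rise_time) / 3
  a_slow <- plateau_flow * exp(3)
  flow_model <- function(tau) {
    ifelse(tt <= rise_time,
           pef * sin(pi * tt / (2 * rise_time)),
           (pef - a_slow) * exp(-(tt - rise_time) / tau) +
             if (a_slow > 0) a_slow * exp(-(tt - rise_time) / tau_slow) else 0)
  }
  if (is.null(tau)) {
    vol_end <- function(tau) {
      f <- flow_model(tau)
      sum(diff(tt) * (f[-1] + f[-length(f)]) / 2)
    }
    lo <- 1e-3
    hi <- 100
    if (vol_end(lo) >= fvc || vol_end(hi) <= fvc) {
      stop_input("infeasible (fvc, pef, duration) combination: ",
                 "no positive decay constant reaches the requested FVC")
    }
    tau <- uniroot(function(x) vol_end(x) - fvc, c(lo, hi),
                   tol = 1e-7)$root
  }
  flow <- flow_model(tau)
  add_noise <- function() flow + rnorm(length(flow), 0, noise_sd)
  if (noise_sd > 0) {
    flow <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  }
  maneuver(time = tt, flow = flow, sample_rate = sample_rate,
           meta = list(kind = "clean", fvc = fvc, pef = pef,
                       rise_time = rise_time, tau = tau,
                       duration = duration, noise_sd = noise_sd,
                       seed = if (is.null(seed)) NA else seed))
}

# band-limited noise over a sample window, realized sd normalized to
# `target_sd` inside the window so the injected energy is exact
band_noise <- function(n_total, window, fs, target_sd, band = c(8, 12)) {
  if (length(window) < 4L || target_sd <= 0) return(numeric(n_total))
  x <- rnorm(n_total)
  ny <- fs / 2
  bf <- signal::butter(2, band / ny, type = "pass")
  x <- as.numeric(signal::filtfilt(bf, x))
  w <- numeric(n_total)
  xs <- x[window] - mean(x[window])
  s <- sd(xs)
  if (s < 1e-12) return(numeric(n_total))
  w[window] <- xs * (target_sd / s)
  w
}

#' Inject a labeled defect into a maneuver
#'
#' Applies one of nine morphological defects, scaled by `severity` in
#' `[0, 1]`; severity 0 returns the input unchanged. The magnitudes are
#' anchored to the printed acceptability thresholds (0.15 L
#' back-extrapolated volume, 0.025 L end-of-test volume, 6 s expiratory
#' time) so that severity 1 violates the designated criterion decisively
#' while severity 0.2 stays within bounds:
#' \describe{
#'   \item{delayed_start}{prepends a 1-s slow leak expiring
#'     `severity * 0.5` L before the blast.}
#'   \item{cough}{multiplies flow by `1 - severity * g(t)` with a narrow
#'     Gaussian (sd 40 ms) at `location` (default: where the descending
#'     flow reaches half of PEF), carving a transient valley with a
#'     rebound peak.}
#'   \item{bimodal_peak}{a brief flow interruption just after the peak
#'     followed by a recovery: a Gaussian dip (depth
#'     `severity * 0.25 * PEF`) where the descent crosses 90% of PEF and
#'     a Gaussian bump (height `severity * 0.2 * PEF`) at the 75%
#'     crossing, producing a distinct second mode just below PEF.}
#'   \item{flat_peak}{clips the peak to `(1 - 0.1 * severity) * PEF` and
#'     holds that level over a forward plateau of `0.6 * severity` s,
#'     with a smooth shoulder back to the descent.}
#'   \item{slow_peak}{time-stretches the rise so the time to peak grows by
#'     the factor `1 + 4 * severity`.}
#'   \item{early_termination}{truncates the record at
#'     `duration * (1 - 0.6 * severity)`.}
#'   \item{end_oscillation}{adds a `severity * 0.1` L/s, 4-Hz sinusoid
#'     over the final second.}
#'   \item{irregular_ascent, irregular_descent}{add band-limited noise of
#'     sd `severity * 0.05 * PEF`, restricted to the ascent (onset to
#'     peak; 15-30 Hz so several ripple cycles fit in the short rise) or
#'     the descent (peak band to the final second; 8-12 Hz).}
#' }
#'
#' @param mnv A [maneuver()].
#' @param kind One of the nine defect kinds (see Details).
#' @param severity Defect severity in `[0, 1]`.
#' @param location Optional defect location (s) for `cough`.
#' @param seed Integer seed for the stochastic defects (irregular ascent /
#'   descent); `NULL` uses the current RNG state.
#' @return A new [maneuver()]; `meta$defect` records kind and severity.
#' @export
inject_defect <- function(mnv, kind, severity, location = NULL, seed = NULL) {
  if (!kind %in% DEFECT_KINDS) {
    stop_input("unknown defect kind: ", kind)
  }
  if (severity < 0 || severity > 1) stop_input("severity must be in [0, 1]")
  if (severity == 0) return(mnv)

  dt <- 1 / mnv$sample_rate
  tt <- mnv$time
  flow <- mnv$flow
  n <- length(flow)
  pef_idx <- which.max(flow)
  pef <- flow[pef_idx]
  t_pef <- tt[pef_idx]
  t_end <- tt[n]

  apply_kind <- function() {
    switch(kind,
      delayed_start = {
        t_leak <- seq(0, 1 - dt, by = dt)
        leak <- (pi / 2) * (severity * 0.5) * sin(pi * t_leak / 1)
        flow <<- c(leak, flow)
      },
      cough = {
        # default: mid-descent in the flow-volume sense, where flow has
        # fallen to half of PEF (a time-based default would land on the
        # near-empty tail of fast exhalations)
        loc <- if (is.null(location)) {
          half <- which(tt > t_pef & flow <= 0.5 * pef)
          if (length(half)) tt[half[1]] else t_pef + 0.3 * (t_end - t_pef)
        } else location
        g <- exp(-(tt - loc)^2 / (2 * 0.04^2))
        flow <<- flow * (1 - severity * g)
      },
      bimodal_peak = {
        # brief flow interruption right after the peak followed by a
        # recovery bump: a dip centered where the descent crosses 90% of
        # PEF and a bump at the 75% crossing, widths tied to the local
        # decay rate so the second mode stays inside the peak band
        t_a <- tt[which(tt > t_pef & flow <= 0.90 * pef)[1]]
        if (is.na(t_a)) t_a <- t_pef + 0.05
        t_b <- tt[which(tt > t_pef & flow <= 0.75 * pef)[1]]
        t_b <- max(if (is.na(t_b)) -Inf else t_b, t_a + 0.08)
        sg <- max(0.03, (t_b - t_a) / 2)
        flow <<- flow +
          severity * pef * (0.20 * exp(-(tt - t_b)^2 / (2 * sg^2)) -
                              0.25 * exp(-(tt - t_a)^2 / (2 * sg^2)))
      },
      flat_peak = {
        # the subject holds a slightly depressed peak: clip the top and
        # sustain the clip level forward over a widening plateau with a
        # half-cosine shoulder back to the natural descent
        clip <- (1 - 0.1 * severity) * pef
        w <- 0.6 * severity
        ramp <- 0.15
        d <- tt - t_pef
        env <- ifelse(d >= 0 & d <= w, clip,
                      ifelse(d > w & d <= w + ramp,
                             clip * 0.5 * (1 + cos(pi * (d - w) / ramp)),
                             0))
        flow <<- pmax(pmin(flow, clip), env)
      },
      slow_peak = {
        stretch <- 1 + 4 * severity
        r_new <- t_pef * stretch
        t_rise <- seq(0, r_new, by = dt)
        rise <- approx(tt[tt <= t_pef], flow[tt <= t_pef],
                       t_rise / stretch, rule = 2)$y
        flow <<- c(rise, flow[tt > t_pef])
      },
      early_termination = {
        keep <- tt <= t_end * (1 - 0.6 * severity)
        flow <<- flow[keep]
      },
      end_oscillation = {
        w <- tt >= t_end - 1
        flow[w] <<- flow[w] + severity * 0.1 * sin(2 * pi * 4 * (tt[w] - (t_end - 1)))
      },
      irregular_ascent = {
        # the ripple band scales with the short ascent window (15-30 Hz
        # puts 2-4 cycles inside the rise); slower components would fit
        # under a smooth rise and not constitute an irregularity
        onset <- which(flow >= 0.02 * pef)[1]
        win <- seq.int(onset, pef_idx)
        flow <<- flow + band_noise(n, win, mnv$sample_rate,
                                   severity * 0.05 * pef, band = c(15, 30))
      },
      irregular_descent = {
        start <- which(tt > t_pef & flow <= 0.8 * pef)[1]
        if (is.na(start)) start <- pef_idx + 1L
        stop_i <- max(start + 4L, which(tt >= t_end - 1)[1] - 1L)
        win <- seq.int(start, min(stop_i, n))
        flow <<- flow + band_noise(n, win, mnv$sample_rate,
                                   severity * 0.05 * pef)
      })
  }
  if (is.null(seed)) apply_kind() else withr::with_seed(seed, apply_kind())

  meta <- mnv$meta
  meta$defect <- kind
  meta$severity <- severity
  maneuver(time = seq(0, by = dt, length.out = length(flow)),
           flow = flow, sample_rate = mnv$sample_rate, meta = meta)
}

#' Generate a labeled synthetic dataset
#'
#' Draws clean maneuvers (expert label 1) and high-severity defect
#' maneuvers (expert label 0, severity uniform in `severity_range`) with
#' physiologically coupled parameters: FVC uniform on 2-6 L, PEF close to
#' twice FVC (jittered by +/-20% and clamped to 4-12 L/s, reflecting the
#' strong association between vital capacity and attainable peak flow),
#' rise time uniform on 0.08-0.15 s and exhalation duration uniform on
#' 8-11 s. Fully reproducible from `master_seed`.
#'
#' @param n_clean Number of clean maneuvers.
#' @param n_per_defect Number of maneuvers per defect kind.
#' @param master_seed Integer seed governing every draw.
#' @param severity_range Range of defect severities (default high: 0.8-1).
#' @param noise_sd Flow noise sd (L/s) for all curves.
#' @param sample_rate Sampling rate (Hz).
#' @return A list of class `spiro_dataset` with elements `maneuvers` (list
#'   of [maneuver()]), `labels` (0/1), and `manifest` (a data frame with
#'   id, label, defect kind, severity and seed per curve).
#' @export
generate_labeled_dataset <- function(n_clean, n_per_defect, master_seed = 1L,
                                     severity_range = c(0.8, 1),
                                     noise_sd = 0.02, sample_rate = 100) {
  if (n_clean < 0 || n_per_defect < 0) stop_input("counts must be >= 0")
  total <- n_clean + n_per_defect * length(DEFECT_KINDS)
  if (total == 0) {
    manifest <- data.frame(id = character(0), label = integer(0),
                           defect = character(0), severity = numeric(0),
                           seed = integer(0))
    return(structure(list(maneuvers = list(), labels = integer(0),
                          manifest = manifest),
                     class = "spiro_dataset"))
  }
  withr::with_seed(master_seed, {
    maneuvers <- vector("list", total)
    kinds <- c(rep("clean", n_clean),
               rep(DEFECT_KINDS, each = n_per_defect))
    rows <- vector("list", total)
    for (i in seq_len(total)) {
      fvc <- runif(1, 2, 6)
      pef <- min(12, max(4, 2 * fvc * runif(1, 0.8, 1.25)))
      rise <- runif(1, 0.08, 0.15)
      dur <- runif(1, 8, 11)
      sev <- if (kinds[i] == "clean") 0 else runif(1, severity_range[1], severity_range[2])
      seed_i <- sample.int(.Machine$integer.max - 1L, 1)
      m <- generate_clean(fvc, pef, rise, duration = dur,
                          sample_rate = sample_rate, noise_sd = noise_sd,
                          seed = seed_i)
      if (kinds[i] != "clean") {
        m <- inject_defect(m, kinds[i], sev, seed = seed_i + 1L)
      }
      maneuvers[[i]] <- m
      rows[[i]] <- data.frame(id = sprintf("m%04d", i),
                              label = if (kinds[i] == "clean") 1L else 0L,
                              defect = kinds[i], severity = sev,
                              seed = seed_i)
    }
    manifest <- do.call(rbind, rows)
    structure(list(maneuvers = maneuvers, labels = manifest$label,
                   manifest = manifest),
              class = "spiro_dataset")
  })
}

#' @export
print.spiro_dataset <- function(x, ...) {
  cat(sprintf("<spiro_dataset> %d maneuvers (%d clean, %d defective)\n",
              length(x$maneuvers), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}
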