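#' Construct a forced-expiration maneuver
#'
#' A maneuver is one forced-expiration recording: sample times (s), expiratory
#' flow (L/s, positive) and cumulative expired volume (L) on a common uniform
#' time base. Either flow or volume may be omitted: the missing series is
#' reconstructed from the other (trapezoidal integration, respectively
#' finite-difference differentiation). Non-uniformly sampled input is
#' resampled to `resample_rate` by linear interpolation.
#'
#' @param time Numeric vector of sample times (s), strictly increasing.
#' @param flow Numeric vector of expiratory flow (L/s) or `NULL`.
#' @param volume Numeric vector of cumulative expired volume (L) or `NULL`.
#' @param sample_rate Sampling rate in Hz; inferred from `time` if `NULL`.
#' @param meta Named list of free-form identifiers (subject id, trial, ...).
#' @param resample_rate Target rate (Hz) used when the input spacing is not
#'   uniform to within 1% relative tolerance.
#' @return An object of class `maneuver` with elements `time`, `flow`,
#'   `volume`, `sample_rate`, `meta`.
#' @export
maneuver <- function(time, flow = NULL, volume = NULL, sample_rate = NULL,
                     meta = list(), resample_rate = 100) {
  if (is.null(flow) && is.null(volume)) {
    stop_input("at least one of flow or volume must be supplied")
  }
  n <- length(time)
  if (n < 10L) stop_input("a maneuver needs at least 10 samples")
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  for (s in list(flow, volume)) {
    if (!is.null(s) && length(s) != n) {
      stop_input("time, flow and volume must have identical length")
    }
  }

  dt <- diff(time)
  uniform <- (max(dt) - min(dt)) <= 0.01 * mean(dt)
  if (!uniform) {
    new_time <- seq(time[1], time[n], by = 1 / resample_rate)
    if (!is.null(flow)) flow <- approx(time, flow, new_time, rule = 2)$y
    if (!is.null(volume)) volume <- approx(time, volume, new_time, rule = 2)$y
    time <- new_time
    n <- length(time)
    sample_rate <- resample_rate
  }
  if (is.null(sample_rate)) sample_rate <- 1 / mean(diff(time))

  if (is.null(volume)) volume <- integrate_flow(flow, time)
  if (is.null(flow)) flow <- differentiate(volume, time, order = 1L)
  if (abs(volume[1]) > 0.05) {
    stop_input("volume must start within 0.05 L of zero (got ",
               signif(volume[1], 3), " L)")
  }

  structure(
    list(time = as.numeric(time), flow = as.numeric(flow),
         volume = as.numeric(volume), sample_rate = sample_rate, meta = meta),
    class = "maneuver")
}

#' @export
print.maneuver <- function(x, ...) {
  cat(sprintf(
    "<maneuver> %d samples @ %.4g Hz, %.2f s, max volume %.2f L, max flow %.2f L/s\n",
    length(x$time), x$sample_rate, x$time[length(x$time)] - x$time[1],
    max(x$volume), max(x$flow)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Resample a maneuver to a new uniform rate
#'
#' Linear interpolation of flow and volume onto a uniform grid at `rate` Hz
#' over the original time span.
#'
#' @param mnv A [maneuver()].
#' @param rate Target sampling rate (Hz).
#' @return A resampled `maneuver`.
#' @export
resample_maneuver <- function(mnv, rate) {
  tt <- seq(mnv$time[1], mnv$time[length(mnv$time)], by = 1 / rate)
  maneuver(time = tt,
           flow = approx(mnv$time, mnv$flow, tt, rule = 2)$y,
           volume = approx(mnv$time, mnv$volume, tt, rule = 2)$y,
           sample_rate = rate, meta = mnv$meta)
}
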