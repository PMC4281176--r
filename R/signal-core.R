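#' Cumulative trapezoidal integration of a flow signal
#'
#' Converts an expiratory flow signal (L/s) into cumulative expired volume
#' (L) by the trapezoidal rule, anchored at zero volume at the first sample.
#'
#' @param flow Numeric vector of flow values (L/s, expiratory positive).
#' @param time Numeric vector of sample times (s), strictly increasing, same
#'   length as `flow`.
#' @return Numeric vector of cumulative volume (L), same length as `flow`,
#'   with `volume[1] == 0`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' v <- integrate_flow(rep(1, length(t)), t)
#' tail(v, 1)  # 1 L expired at constant 1 L/s for 1 s
#' @export
integrate_flow <- function(flow, time) {
  if (length(flow) != length(time)) {
    stop_input("flow and time must have the same length")
  }
  if (length(time) < 2L || any(diff(time) <= 0)) {
    stop_input("time must be strictly increasing with at least 2 samples")
  }
  dt <- diff(time)
  c(0, cumsum(dt * (flow[-1] + flow[-length(flow)]) / 2))
}

#' Finite-difference differentiation of a uniformly sampled signal
#'
#' First or second derivative by central differences on the interior and
#' one-sided differences at the endpoints. Length is preserved.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param time Numeric vector of sample times (s), uniform spacing.
#' @param order Derivative order, 1 or 2.
#' @return Numeric vector of the derivative, same length as `x`.
#' @export
differentiate <- function(x, time, order = 1L) {
  if (!order %in% c(1L, 2L)) stop_input("order must be 1 or 2")
  n <- length(x)
  if (n != length(time)) stop_input("signal and time must have the same length")
  if (n < 3L) stop_input("need at least 3 samples to differentiate")
  dt <- mean(diff(time))
  if (order == 1L) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    d
  } else {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
    d[1] <- d[2]
    d[n] <- d[n - 1]
    d
  }
}

#' Local-quadratic (Savitzky-Golay) smoothing over a time window
#'
#' Least-squares quadratic fit in a sliding window of the stated duration;
#' the classical Savitzky-Golay filter. A zero window is the identity, and
#' polynomials up to degree 2 (in particular constants and ramps) pass
#' through unchanged.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param time Sample times (s), uniform spacing.
#' @param window Smoothing window length in seconds (>= 0).
#' @return Smoothed vector, same length as `x`.
#' @export
smooth_signal <- function(x, time, window) {
  if (window < 0) stop_input("window must be >= 0")
  if (window == 0) return(x)
  dur <- time[length(time)] - time[1]
  if (window > dur) stop_input("smoothing window exceeds record duration")
  dt <- mean(diff(time))
  n <- max(3L, round(window / dt))
  if (n %% 2L == 0L) n <- n + 1L
  if (n >= length(x)) return(x)
  as.numeric(signal::sgolayfilt(x, p = 2, n = n))
}
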