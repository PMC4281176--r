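# -- internal helpers for the shape criteria ---------------------------------

# Flow re-gridded onto a uniform expired-volume axis over a sample range.
# Returns list(v, f, dv) or NULL when the volume span is too small to grid.
# Non-increasing volume samples (sensor noise near zero flow) are dropped.
fv_grid <- function(mnv, idx, n_grid = NULL) {
  v <- mnv$volume[idx]
  f <- mnv$flow[idx]
  # strictly-increasing subsequence of the volume samples
  keep <- logical(length(v))
  m <- -Inf
  for (i in seq_along(v)) {
    if (v[i] > m + 1e-9) {
      keep[i] <- TRUE
      m <- v[i]
    }
  }
  v <- v[keep]
  f <- f[keep]
  if (length(v) < 5L || v[length(v)] - v[1] < 1e-3) return(NULL)
  if (is.null(n_grid)) n_grid <- max(20L, length(v))
  vg <- seq(v[1], v[length(v)], length.out = n_grid)
  fg <- approx(v, f, vg)$y
  list(v = vg, f = fg, dv = vg[2] - vg[1])
}

# dF/dV along the sampled curve: smoothed dF/dt divided by flow (= dV/dt),
# evaluated only where flow is above a floor fraction of PEF.
fv_slope <- function(mnv, idx, cfg, pef, floor_frac = cfg$c7_flow_floor) {
  fs <- smooth_signal(mnv$flow, mnv$time, cfg$smoothing_window)
  dfdt <- differentiate(fs, mnv$time, 1L)
  ok <- idx[fs[idx] >= floor_frac * pef]
  if (length(ok) < 3L) return(NULL)
  list(idx = ok, slope = dfdt[ok] / fs[ok], volume = mnv$volume[ok])
}

# count sign changes of x, ignoring entries with |x| below floor
count_sign_changes <- function(x, floor = 0) {
  s <- sign(x)
  s[abs(x) < floor] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# Local maxima of x with topographic prominence >= min_prom.
# Prominence of a peak: its height minus the higher of the two minima
# separating it from the nearest higher ground (record edges count as
# higher ground at -Inf, i.e. edge peaks use the global span on that side).
# Ties in height are resolved to the earliest sample.
find_prominent_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  is_pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(is_pk)) return(integer(0))
  prom <- vapply(is_pk, function(i) {
    h <- x[i]
    # walk left until higher ground
    left <- x[seq_len(i - 1L)]
    hl <- which(left > h)
    lmin <- if (length(hl)) min(x[(max(hl) + 1L):(i - 1L)]) else min(left)
    right <- x[(i + 1L):n]
    hr <- which(right > h)
    rmin <- if (length(hr)) min(right[seq_len(min(hr) - 1L)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  is_pk[prom >= min_prom]
}

criterion_result <- function(id, metrics, thresholds, outcome,
                             reason = NULL) {
  stopifnot(outcome %in% c("pass", "fail", "not_applicable"))
  structure(list(criterion_id = id,
                 metrics = metrics, thresholds = thresholds,
                 outcome = outcome, reason = reason),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("<criterion %s> %s\n", x$criterion_id, x$outcome))
  if (length(x$metrics)) {
    cat("  metrics:",
        paste(names(x$metrics), signif(unlist(x$metrics), 4), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

not_applicable <- function(id, reason) {
  criterion_result(id, metrics = list(), thresholds = list(),
                   outcome = "not_applicable", reason = reason)
}

verdict <- function(fail) if (isTRUE(fail)) "fail" else "pass"
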