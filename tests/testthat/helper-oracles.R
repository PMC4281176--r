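# Independent brute-force oracles and constructed boundary curves.
# These deliberately avoid the package's own smoothing/derivative path.

# exhaustive-tangent oracle: slope at every sample by plain central
# difference of volume; report the axis crossing for the max-slope sample
oracle_t_zero <- function(mnv) {
  v <- mnv$volume
  t <- mnv$time
  n <- length(v)
  s <- c((v[2] - v[1]) / (t[2] - t[1]),
         (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
         (v[n] - v[n - 1]) / (t[n] - t[n - 1]))
  i <- which.max(s)
  t[i] - v[i] / s[i]
}

oracle_bev <- function(mnv, t_zero) {
  max(0, approx(mnv$time, mnv$volume, t_zero, rule = 2)$y)
}

# dense-grid window max-min oracle for the end-of-test volume
oracle_eotv <- function(mnv, window = 1.0) {
  t_end <- mnv$time[length(mnv$time)]
  tg <- seq(t_end - window, t_end, length.out = 2000)
  vg <- approx(mnv$time, mnv$volume, tg)$y
  max(vg) - min(vg)
}

oracle_fet100 <- function(mnv, t_zero) {
  i <- which(mnv$volume >= max(mnv$volume))[1]
  mnv$time[i] - t_zero
}

# dense-grid Riemann-sum integration oracle
oracle_cum_volume <- function(flow_fun, t_query, oversample = 1000) {
  vapply(t_query, function(tq) {
    if (tq <= 0) return(0)
    tg <- seq(0, tq, length.out = max(2, ceiling(tq * oversample)))
    sum(flow_fun(tg)) * (tg[2] - tg[1])
  }, numeric(1))
}

# parameter draws matching the labeled-dataset study conditions
draw_clean_params <- function() {
  fvc <- runif(1, 2, 6)
  list(fvc = fvc,
       pef = min(12, max(4, 2 * fvc * runif(1, 0.8, 1.25))),
       rise = runif(1, 0.08, 0.15),
       dur = runif(1, 8, 11))
}

random_clean <- function(seed) {
  p <- draw_clean_params()
  generate_clean(p$fvc, p$pef, p$rise, duration = p$dur, noise_sd = 0.02,
                 seed = seed)
}

# constructed curve with an exactly controllable back-extrapolated volume:
# a 1-s constant leak `a`, a constant-flow blast (slope 8 L/s, so every
# blast tangent crosses zero volume at t = 1 - a/8), then a decay.
# closed-form BEV = a * (1 - a / 8).
make_bev_curve <- function(a, duration = 10, fs = 100) {
  tt <- seq(0, duration, by = 1 / fs)
  flow <- ifelse(tt < 1, a,
                 ifelse(tt < 1.2, 8, 8 * exp(-(tt - 1.2) / 0.12)))
  maneuver(time = tt, flow = flow, sample_rate = fs)
}

# constructed curve whose final-second volume accumulation is exactly x:
# a decayed blast that is empty by 6 s, then constant flow x over the
# final second
make_eotv_curve <- function(x, duration = 8, fs = 100) {
  tt <- seq(0, duration, by = 1 / fs)
  flow <- ifelse(tt < 0.15, 8 * sin(pi * tt / 0.3),
                 8 * exp(-(tt - 0.15) / 0.4))
  flow[tt >= duration - 1] <- x
  maneuver(time = tt, flow = flow, sample_rate = fs)
}

# constructed curve reaching its maximum volume exactly at t_f, with a
# constant-flow blast from t = 0 so T_zero is exactly 0
make_fet_curve <- function(t_f, duration = 12, fs = 100) {
  tt <- seq(0, duration, by = 1 / fs)
  flow <- ifelse(tt <= 0.35, 8, 0.2)
  flow[tt > t_f] <- 0
  maneuver(time = tt, flow = flow, sample_rate = fs)
}

zone_seq <- function(iv) {
  if (iv[2] <= iv[1]) integer(0) else seq.int(iv[1], iv[2] - 1L)
}

criterion_by_id <- function(results, id) {
  for (r in results) if (r$criterion_id == id) return(r)
  NULL
}
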