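test_that("the back-extrapolated origin of ramp volumes is the ramp foot", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  # pure ramp through the origin
  m <- maneuver(time = t, volume = 2 * t, sample_rate = fs)
  expect_lt(abs(compute_t_zero(m)), 1 / fs + 1e-9)

  # ramp starting at t = 0.5
  m2 <- maneuver(time = t, volume = pmax(0, 2 * (t - 0.5)), sample_rate = fs)
  expect_lt(abs(compute_t_zero(m2) - 0.5), 0.02)

  m3 <- maneuver(time = t, flow = rep(0, length(t)), sample_rate = fs)
  expect_error(compute_t_zero(m3), class = "spiroqc_degenerate_error")
})

test_that("the tangent origin agrees with the exhaustive-tangent oracle", {
  set.seed(101)
  for (i in 1:50) {
    p <- draw_clean_params()
    m <- generate_clean(p$fvc, p$pef, p$rise, duration = p$dur, noise_sd = 0)
    dt <- 1 / m$sample_rate
    expect_lt(abs(compute_t_zero(m) - oracle_t_zero(m)), 2 * dt)
  }
})

test_that("generator parameters are recovered by the index computations", {
  m <- generate_clean(4, 8, 0.1, duration = 10, noise_sd = 0,
                      plateau_flow = 0)
  idx <- compute_indices(m)
  expect_lt(abs(idx$FVC - 4), 0.02)
  expect_lt(abs(idx$PEF - 8), 0.01)
  expect_lte(idx$EOTV, 1e-3)
})

test_that("FEV1/FVC of a saturating-exponential volume matches the closed form", {
  tau <- 0.5
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)
  m <- maneuver(time = t, volume = 4 * (1 - exp(-t / tau)), sample_rate = fs)
  t0 <- oracle_t_zero(m)
  idx <- compute_indices(m)
  ratio <- (approx(t, m$volume, t0 + 1)$y - approx(t, m$volume, t0)$y) / 4
  analytic <- exp(-t0 / tau) * (1 - exp(-1 / tau))
  expect_lt(abs(ratio - analytic), 1e-3)
  # implementation FEV1 relative to its own origin agrees too
  expect_lt(abs(idx$FEV1 / idx$FVC - analytic), 2e-3)
})

test_that("a volume constant over the final second has zero end-of-test volume", {
  fs <- 100
  t <- seq(0, 8, by = 1 / fs)
  flow <- ifelse(t < 0.2, 40 * t, 8 * exp(-(t - 0.2) / 0.4))
  flow[t >= 7] <- 0
  m <- maneuver(time = t, flow = flow, sample_rate = fs)
  expect_equal(compute_indices(m)$EOTV, 0)
})

test_that("FEV1 and EOTV are flagged when the record is too short", {
  fs <- 100
  t <- seq(0, 0.9, by = 1 / fs)
  m <- maneuver(time = t, flow = 4 * sin(pi * t / 0.9), sample_rate = fs)
  idx <- compute_indices(m)
  expect_true(is.na(idx$FEV1))
  expect_identical(idx$fev1_reason, "record_too_short")
  expect_true(is.na(idx$EOTV))
})

test_that("index invariants hold across random maneuvers", {
  set.seed(77)
  for (i in 1:25) {
    m <- random_clean(seed = 7000 + i)
    idx <- compute_indices(m)
    expect_gte(idx$FEV1, 0)
    expect_lte(idx$FEV1, idx$FVC)
    expect_gte(idx$PEF, max(m$flow) - 1e-12)
    expect_gte(idx$BEV, 0)
    expect_gte(idx$EOTV, 0)
    expect_gte(idx$FET100, 0)
    expect_gte(idx$PEFT, -idx$T_zero - 1e-9)
  }
})

test_that("FVC, PEF and FET100 are stable under resampling to 500 Hz", {
  set.seed(55)
  for (i in 1:10) {
    p <- draw_clean_params()
    m <- generate_clean(p$fvc, p$pef, p$rise, duration = p$dur, noise_sd = 0)
    m5 <- resample_maneuver(m, 500)
    a <- compute_indices(m)
    b <- compute_indices(m5)
    expect_lt(abs(a$FVC - b$FVC) / a$FVC, 0.01)
    expect_lt(abs(a$PEF - b$PEF) / a$PEF, 0.01)
    expect_lt(abs(a$FET100 - b$FET100) / a$FET100, 0.01)
  }
})
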