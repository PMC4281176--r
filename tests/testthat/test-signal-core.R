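test_that("trapezoidal integration handles constant, zero and ramp flows", {
  t <- seq(0, 1, by = 0.01)
  v <- integrate_flow(rep(1, length(t)), t)
  expect_equal(v[1], 0)
  expect_lt(abs(v[length(v)] - 1), 1e-6)
  expect_true(all(diff(v) >= 0))

  expect_equal(integrate_flow(rep(0, length(t)), t), rep(0, length(t)))

  # triangular ramp 0 -> 2 -> 0 L/s over 2 s, checked against a dense
  # Riemann-sum oracle
  t2 <- seq(0, 2, by = 0.01)
  tri <- function(x) ifelse(x <= 1, 2 * x, 2 * (2 - x))
  v2 <- integrate_flow(tri(t2), t2)
  expect_lt(abs(v2[length(v2)] - 2), 1e-3)
  ref <- oracle_cum_volume(tri, t2[seq(10, 200, by = 10)])
  expect_lt(max(abs(v2[seq(10, 200, by = 10)] - ref)), 1e-3)
})

test_that("integration rejects malformed input", {
  expect_error(integrate_flow(1:5, 1:4), class = "spiroqc_input_error")
  expect_error(integrate_flow(1:4, c(1, 3, 2, 4)),
               class = "spiroqc_input_error")
})

test_that("finite differences recover linear, constant and sinusoid derivatives", {
  t <- seq(0, 1, by = 0.001)
  expect_lt(max(abs(differentiate(3 * t, t)[2:1000] - 3)), 1e-9)
  expect_equal(differentiate(rep(2, length(t)), t), rep(0, length(t)))
  expect_equal(differentiate(rep(2, length(t)), t, order = 2L),
               rep(0, length(t)))

  d <- differentiate(sin(2 * pi * t), t)
  expect_lt(max(abs(d[2:1000] - 2 * pi * cos(2 * pi * t[2:1000]))), 1e-3)

  expect_error(differentiate(t, t, order = 3), class = "spiroqc_input_error")
})

test_that("integration and differentiation round-trip band-limited flow", {
  t <- seq(0, 4, by = 1 / 500)
  f <- 2 + sin(2 * pi * 2 * t) + 0.5 * cos(2 * pi * 3 * t)
  f_back <- differentiate(integrate_flow(f, t), t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(f_back[interior] - f[interior])) / max(abs(f)), 1e-3)
})

test_that("local-quadratic smoothing is identity on polynomials and zero windows", {
  t <- seq(0, 2, by = 0.01)
  x <- rep(3.7, length(t))
  expect_equal(smooth_signal(x, t, 0.05), x)
  ramp <- 1 + 2 * t
  expect_lt(max(abs(smooth_signal(ramp, t, 0.1) - ramp)), 1e-9)
  y <- rnorm(length(t))
  expect_identical(smooth_signal(y, t, 0), y)
  expect_error(smooth_signal(y, t, 5), class = "spiroqc_input_error")
})

test_that("smoothing matches an independent per-window least-squares fit and damps impulses", {
  set.seed(3)
  t <- seq(0, 1, by = 0.01)
  x <- rnorm(length(t), sd = 0.1)
  x[50] <- x[50] + 5
  sm <- smooth_signal(x, t, 0.05)
  expect_lt(abs(sm[50] - mean(x[50])), abs(5))  # impulse strictly reduced
  expect_lt(sm[50], x[50])

  # interior samples equal the centered quadratic least-squares fit
  for (i in c(20, 50, 80)) {
    w <- (i - 2):(i + 2)
    fit <- lm(x[w] ~ poly(w, 2, raw = TRUE))
    expect_equal(sm[i], unname(predict(fit)[3]), tolerance = 1e-8)
  }
})
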