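eval_all <- function(m, cfg = default_config()) evaluate_criteria(m, cfg)

outcome <- function(res, id) criterion_by_id(res, id)$outcome

test_that("clean maneuvers pass the whole battery across seeds", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_clean(seed = 1100 + i)
    res <- eval_all(m)
    failed <- vapply(res, function(r) r$outcome == "fail", logical(1))
    expect_true(!any(failed),
                info = paste("seed", 1100 + i, "failed:",
                             paste(vapply(res[failed], `[[`, "",
                                          "criterion_id"), collapse = " ")))
  }
})

test_that("ascent criteria flag injected ripple and go not-applicable on short rises", {
  m <- generate_clean(4, 8, 0.12, duration = 9, noise_sd = 0.02, seed = 21)
  d <- inject_defect(m, "irregular_ascent", 1, seed = 22)
  res <- eval_all(d)
  expect_identical(outcome(res, "C2a"), "fail")

  # too-short Z1: all three ascent criteria not applicable
  idx <- compute_indices(m)
  seg <- segment_zones(m, idx)
  seg$z1 <- c(seg$pef_idx - 2L, seg$pef_idx + 1L)
  short <- evaluate_z1(m, seg, idx, default_config())
  expect_true(all(vapply(short, `[[`, "", "outcome") == "not_applicable"))
})

test_that("peak-timing criteria use the back-extrapolated origin", {
  m <- generate_clean(4, 8, 0.1, duration = 9, noise_sd = 0.02, seed = 31)
  res <- eval_all(m, default_config(peft_max = 0.3))
  expect_identical(outcome(res, "C3"), "pass")
  expect_identical(outcome(res, "C4"), "pass")

  late <- inject_defect(m, "slow_peak", 1)
  expect_identical(outcome(eval_all(late), "C3"), "fail")
})

test_that("flat and bimodal peak shapes are flagged in the peak zone", {
  m <- generate_clean(4.5, 9, 0.1, duration = 9, noise_sd = 0.02, seed = 41)
  res_flat <- eval_all(inject_defect(m, "flat_peak", 1))
  expect_identical(outcome(res_flat, "C5a"), "fail")
  res_bi <- eval_all(inject_defect(m, "bimodal_peak", 1))
  expect_identical(outcome(res_bi, "C5c"), "fail")

  # slow peak: low PEF relative to FVC trips the height check
  low <- generate_clean(5, 4.2, 0.12, duration = 10, noise_sd = 0.02,
                        seed = 42)
  expect_identical(outcome(eval_all(low), "C6"), "fail")
})

test_that("descent criteria flag irregular and interrupted descents", {
  m <- generate_clean(4, 8, 0.1, duration = 9, noise_sd = 0.02, seed = 51)
  res_ir <- eval_all(inject_defect(m, "irregular_descent", 1, seed = 52))
  expect_identical(outcome(res_ir, "C7b"), "fail")
  expect_identical(outcome(res_ir, "C7d"), "fail")

  res_cough <- eval_all(inject_defect(m, "cough", 1))
  expect_identical(outcome(res_cough, "C7a"), "fail")
})

test_that("single-peak criteria flag coughs, including near the FEV1 point", {
  m <- generate_clean(4, 8, 0.1, duration = 9, noise_sd = 0.02, seed = 61)
  res <- eval_all(inject_defect(m, "cough", 1))
  expect_identical(outcome(res, "C12a"), "fail")

  # place the cough so its rebound peak sits at the FEV1 volume; use a
  # slowly emptying curve so flow is still substantial at that volume
  m2 <- generate_clean(6, 6, 0.12, duration = 10, noise_sd = 0.02, seed = 62)
  idx <- compute_indices(m2)
  v_fev1 <- idx$BEV + idx$FEV1
  loc <- m2$time[which(m2$volume >= v_fev1)[1]]
  res_b <- eval_all(inject_defect(m2, "cough", 1, location = loc))
  expect_identical(outcome(res_b, "C12b"), "fail")
})

test_that("every criterion id appears exactly once per evaluation", {
  m <- generate_clean(4, 8, 0.1, duration = 9, noise_sd = 0.02, seed = 71)
  ids <- vapply(eval_all(m), `[[`, "", "criterion_id")
  expect_identical(sort(ids), sort(unique(ids)))
  expect_setequal(ids, c("C1", "C2a", "C2b", "C3", "C4", "C5a", "C5b", "C5c",
                         "C6", "C7a", "C7b", "C7c", "C7d", "C8", "C9",
                         "C10a", "C10b", "C10c", "C10d", "C10e", "C11",
                         "C12a", "C12b", "FET"))
})

test_that("criterion outcomes are deterministic for a fixed maneuver and config", {
  m <- generate_clean(4, 8, 0.1, duration = 9, noise_sd = 0.02, seed = 81)
  expect_identical(eval_all(m), eval_all(m))
})

test_that("session repeatability follows the three-maneuver pair rule", {
  mk <- function(fvc, fev1) {
    structure(list(FVC = fvc, FEV1 = fev1), class = "spiro_indices")
  }
  cfg <- default_config()
  r <- evaluate_repeatability(list(mk(4.00, 3.00), mk(4.10, 3.05),
                                   mk(4.12, 3.08)), cfg = cfg)
  expect_identical(r$outcome, "pass")
  expect_equal(r$metrics$best_dFVC, 0.02)
  expect_equal(r$metrics$best_dFEV1, 0.03)

  r2 <- evaluate_repeatability(list(mk(4, 3), mk(4.01, 3.01)), cfg = cfg)
  expect_identical(r2$outcome, "fail")
  expect_identical(r2$reason, "insufficient maneuvers")

  r3 <- evaluate_repeatability(list(mk(4.0, 3.0), mk(4.2, 3.2),
                                    mk(4.4, 3.4)), cfg = cfg)
  expect_identical(r3$outcome, "fail")

  # a 0.15 L gap is not repeatable (strict inequality)
  r4 <- evaluate_repeatability(list(mk(4.00, 3.00), mk(4.15, 3.00),
                                    mk(5.00, 3.00)), cfg = cfg)
  expect_identical(r4$outcome, "fail")
})
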