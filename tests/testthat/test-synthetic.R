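test_that("the clean generator hits its FVC and PEF targets", {
  m <- generate_clean(4, 8, 0.1, duration = 6, noise_sd = 0)
  idx <- compute_indices(m)
  expect_lt(abs(idx$FVC - 4), 0.01)
  expect_lt(abs(idx$PEF - 8), 0.01)

  set.seed(19)
  for (i in 1:10) {
    p <- draw_clean_params()
    m <- generate_clean(p$fvc, p$pef, p$rise, duration = p$dur, noise_sd = 0)
    idx <- compute_indices(m)
    expect_lt(abs(idx$FVC - p$fvc) / p$fvc, 0.01)
    expect_lt(abs(idx$PEF - p$pef) / p$pef, 0.01)
  }

  expect_error(generate_clean(10, 4, 0.1, duration = 2.5),
               class = "spiroqc_input_error")  # infeasible volume
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_clean(4, 8, 0.1, seed = 42)
  b <- generate_clean(4, 8, 0.1, seed = 42)
  expect_identical(a$flow, b$flow)
  c <- generate_clean(4, 8, 0.1, seed = 43)
  expect_false(identical(a$flow, c$flow))
})

test_that("severity zero is the identity for every defect kind", {
  m <- generate_clean(4, 8, 0.1, seed = 1)
  for (k in names(designated_criterion())) {
    expect_identical(inject_defect(m, k, 0), m, label = k)
  }
  expect_error(inject_defect(m, "sneeze", 0.5), class = "spiroqc_input_error")
})

test_that("high-severity defects violate the printed thresholds they target", {
  m <- generate_clean(4, 8, 0.1, duration = 10, noise_sd = 0.02, seed = 9)

  d1 <- inject_defect(m, "delayed_start", 1)
  i1 <- compute_indices(d1)
  expect_gt(i1$BEV, max(0.15, 0.05 * i1$FVC))
  res1 <- evaluate_criteria(d1)
  expect_identical(criterion_by_id(res1, "C8")$outcome, "fail")

  d2 <- inject_defect(m, "early_termination", 1)
  i2 <- compute_indices(d2)
  expect_lt(i2$FET100, 6)
  expect_gt(i2$EOTV, 0.025)
  res2 <- evaluate_criteria(d2)
  expect_identical(criterion_by_id(res2, "FET")$outcome, "fail")
  expect_identical(criterion_by_id(res2, "C9")$outcome, "fail")

  d3 <- inject_defect(m, "end_oscillation", 1)
  res3 <- evaluate_criteria(d3)
  expect_identical(criterion_by_id(res3, "C11")$outcome, "fail")
})

test_that("defect transforms preserve physical plausibility", {
  m <- generate_clean(4, 8, 0.1, duration = 9, noise_sd = 0, seed = 2)
  for (k in names(designated_criterion())) {
    d <- inject_defect(m, k, 0.9, seed = 3)
    expect_gte(min(d$flow), -0.2 * max(d$flow), label = k)
    if (!k %in% c("cough", "bimodal_peak", "end_oscillation",
                  "irregular_ascent", "irregular_descent")) {
      # noise-free volume stays non-decreasing except where the defect
      # semantics put oscillation or a valley around near-zero flow
      expect_gte(min(diff(d$volume)), -1e-9, label = k)
    }
  }
})

test_that("labeled datasets are reproducible and correctly labeled", {
  empty <- generate_labeled_dataset(0, 0)
  expect_length(empty$maneuvers, 0)

  small <- generate_labeled_dataset(5, 0, master_seed = 3)
  expect_identical(small$labels, rep(1L, 5))

  a <- generate_labeled_dataset(3, 2, master_seed = 17)
  b <- generate_labeled_dataset(3, 2, master_seed = 17)
  expect_identical(a, b)
  expect_identical(sort(unique(a$manifest$defect[a$labels == 0])),
                   sort(names(designated_criterion())))
  expect_true(all(a$manifest$severity[a$labels == 0] >= 0.8))
})

# the full severity-monotonicity grid lives in test-acceptance.R
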