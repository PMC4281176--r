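fake_result <- function(id, outcome) {
  structure(list(criterion_id = id, metrics = list(x = 1),
                 thresholds = list(x = 2), outcome = outcome, reason = NULL),
            class = "criterion_result")
}

test_that("grades follow the rejecting/warning policy partition", {
  pol <- default_policy()
  all_pass <- lapply(c("C1", "C3", "C8", "C12a", "FET"), fake_result,
                     outcome = "pass")
  expect_identical(assign_grade(all_pass, pol), 1L)

  cough <- c(all_pass, list(fake_result("C12a", "fail")))
  expect_identical(assign_grade(cough, pol), 0L)

  warn <- c(all_pass, list(fake_result("C5b", "fail")))
  expect_identical(assign_grade(warn, pol), 2L)

  # not-applicable never rejects
  na <- c(all_pass, list(fake_result("C8", "not_applicable")))
  expect_identical(assign_grade(na, pol), 1L)

  expect_error(assign_grade(list(), pol), class = "spiroqc_input_error")
})

test_that("adding a failure never improves the grade", {
  pol <- default_policy()
  ids <- c("C1", "C2a", "C5b", "C8", "C9", "C12a", "FET")
  set.seed(4)
  for (rep in 1:30) {
    outcomes <- sample(c("pass", "fail"), length(ids), replace = TRUE)
    res <- Map(fake_result, ids, outcomes)
    g0 <- assign_grade(res, pol)
    flip <- which(outcomes == "pass")
    if (!length(flip)) next
    k <- sample(flip, 1)
    res[[k]] <- fake_result(ids[k], "fail")
    g1 <- assign_grade(res, pol)
    # grade order by quality: 1 best, 2 middle, 0 worst
    rank <- c(`1` = 3L, `2` = 2L, `0` = 1L)
    expect_lte(rank[[as.character(g1)]], rank[[as.character(g0)]])
  }
})

test_that("policies reject overlapping or unknown criterion sets", {
  expect_error(grade_policy(rejecting = "C8", warning = "C8"),
               class = "spiroqc_input_error")
  expect_error(grade_policy(rejecting = "C99"),
               class = "spiroqc_input_error")
  pol <- grade_policy(rejecting = "C8", warning = "C9")
  expect_setequal(c(pol$rejecting, pol$warning, pol$ignored),
                  spiroqc:::ALL_CRITERIA)
})

test_that("confusion statistics follow the grade-0/1 agreement definitions", {
  s <- score_against_labels(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 1)
  expect_equal(s$n_grade2, 0)

  s2 <- score_against_labels(c(0, 2, 1, 0), c(0, 0, 1, 1))
  expect_equal(s2$sensitivity, 0.5)
  expect_equal(s2$specificity, 0.5)

  s3 <- score_against_labels(c(2, 2, 2), c(0, 0, 1))
  expect_equal(s3$sensitivity, 0)
  expect_equal(s3$specificity, 0)

  expect_true(is.na(score_against_labels(c(0, 0), c(0, 0))$specificity))
  expect_error(score_against_labels(c(0, 3), c(0, 1)),
               class = "spiroqc_input_error")
})

test_that("session assessment grades maneuvers and applies repeatability", {
  ms <- lapply(1:3, function(i) {
    generate_clean(4 + 0.02 * i, 8, 0.1, duration = 10, noise_sd = 0.01,
                   seed = 500 + i)
  })
  ses <- assess_session(ms)
  expect_identical(ses$grades, rep(1L, 3))
  expect_identical(ses$repeatability$outcome, "pass")

  # wreck one maneuver: only two acceptable remain
  ms2 <- c(ms[1:2], list(inject_defect(ms[[3]], "cough", 1)))
  ses2 <- assess_session(ms2)
  expect_identical(ses2$grades[3], 0L)
  expect_identical(ses2$repeatability$outcome, "fail")
  expect_identical(ses2$repeatability$reason, "insufficient maneuvers")
})
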