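ALL_CRITERIA <- c("C1", "C2a", "C2b", "C3", "C4", "C5a", "C5b", "C5c", "C6",
                  "C7a", "C7b", "C7c", "C7d", "C8", "C9",
                  "C10a", "C10b", "C10c", "C10d", "C10e",
                  "C11", "C12a", "C12b", "FET", "REP")

#' Grading policy: which criterion failures reject and which warn
#'
#' A failed *rejecting* criterion forces grade 0 (reject); a failed
#' *warning* criterion (with no rejecting failure) yields grade 2 (needs
#' expert review); if nothing fails the maneuver is grade 1 (acceptable).
#' Criteria in neither set are evaluated and reported but ignored for
#' grading.
#'
#' The default routes to *rejecting* the criteria that unambiguously flag a
#' decisively bad maneuver — the hesitant start (C8), the combined
#' end-of-test failure (C10a, which requires the plateau test C9 to fail
#' with a short Tex), the late peak (C3), the flat and bimodal peak shapes
#' (C5a, C5c), the irregular ascent (C2a) and descent (C7b), end-of-test
#' oscillation (C11), the cough signature (C12a) and a short expiratory
#' time (FET). The remaining morphology criteria warn: their failures are
#' subtler shape findings that merit expert review rather than automatic
#' rejection. Both sets are fully configurable.
#'
#' @param rejecting Character vector of criterion ids forcing grade 0.
#' @param warning Character vector of criterion ids yielding grade 2.
#' @return A list of class `grade_policy`.
#' @export
grade_policy <- function(
    rejecting = c("C2a", "C3", "C5a", "C5c", "C7b", "C8", "C10a", "C11",
                  "C12a", "FET"),
    warning = c("C1", "C2b", "C4", "C5b", "C6", "C7a", "C7c", "C7d", "C9",
                "C10b", "C10c", "C10d", "C10e", "C12b")) {
  rejecting <- as.character(rejecting)
  warning <- as.character(warning)
  if (length(intersect(rejecting, warning))) {
    stop_input("a criterion cannot be both rejecting and warning")
  }
  bad <- setdiff(c(rejecting, warning), ALL_CRITERIA)
  if (length(bad)) stop_input("unknown criterion ids: ", paste(bad, collapse = ", "))
  structure(list(rejecting = rejecting, warning = warning,
                 ignored = setdiff(ALL_CRITERIA, c(rejecting, warning))),
            class = "grade_policy")
}

#' @rdname grade_policy
#' @export
default_policy <- function() grade_policy()

#' @export
print.grade_policy <- function(x, ...) {
  cat("<grade_policy>\n")
  cat("  rejecting:", paste(x$rejecting, collapse = " "), "\n")
  cat("  warning:  ", paste(x$warning, collapse = " "), "\n")
  cat("  ignored:  ", paste(x$ignored, collapse = " "), "\n")
  invisible(x)
}

#' Map criterion outcomes to a quality grade
#'
#' Grade 0 (reject) when any rejecting criterion failed; grade 2 (expert
#' review) when any warning criterion failed but no rejecting one; grade 1
#' (acceptable) otherwise. `not_applicable` outcomes never reject.
#'
#' @param criterion_results List of `criterion_result` objects.
#' @param policy A [grade_policy()].
#' @return Integer grade: 0, 1 or 2.
#' @export
assign_grade <- function(criterion_results, policy = default_policy()) {
  if (!length(criterion_results)) stop_input("empty criterion result list")
  ids <- vapply(criterion_results, `[[`, "", "criterion_id")
  out <- vapply(criterion_results, `[[`, "", "outcome")
  failed <- ids[out == "fail"]
  if (any(failed %in% policy$rejecting)) return(0L)
  if (any(failed %in% policy$warning)) return(2L)
  1L
}

#' Assess one maneuver end to end
#'
#' Computes indices, segments the zones, evaluates the full criterion
#' battery and assigns the quality grade.
#'
#' @param mnv A [maneuver()].
#' @param cfg A [default_config()].
#' @param policy A [grade_policy()].
#' @return A list of class `quality_report`: `grade`, `criterion_results`,
#'   `indices`, `config_fingerprint`.
#' @export
assess_maneuver <- function(mnv, cfg = default_config(),
                            policy = default_policy()) {
  indices <- compute_indices(mnv, cfg)
  seg <- segment_zones(mnv, indices, cfg)
  res <- evaluate_criteria(mnv, cfg, indices = indices, seg = seg)
  structure(list(grade = assign_grade(res, policy),
                 criterion_results = res,
                 indices = indices,
                 config_fingerprint = config_fingerprint(cfg)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> grade: %d  (config %s)\n",
              x$grade, x$config_fingerprint))
  cat(sprintf("  FVC %.2f L  FEV1 %s L  PEF %.2f L/s  FET100 %.2f s\n",
              x$indices$FVC,
              ifelse(is.na(x$indices$FEV1), "NA",
                     sprintf("%.2f", x$indices$FEV1)),
              x$indices$PEF, x$indices$FET100))
  tab <- report_table(x)
  failed <- tab$criterion[tab$outcome == "fail"]
  cat("  failed criteria:",
      if (length(failed)) paste(failed, collapse = " ") else "none", "\n")
  invisible(x)
}

#' Tabulate a quality report
#'
#' @param report A [assess_maneuver()] result.
#' @return A data frame with one row per criterion: id, outcome, headline
#'   metric name and value.
#' @export
report_table <- function(report) {
  rows <- lapply(report$criterion_results, function(r) {
    m <- if (length(r$metrics)) r$metrics[[1]] else NA_real_
    mn <- if (length(r$metrics)) names(r$metrics)[1] else NA_character_
    data.frame(criterion = r$criterion_id, outcome = r$outcome,
               metric = mn, value = as.numeric(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assess a session of maneuvers with the repeatability rule
#'
#' Grades each maneuver individually, then evaluates the session
#' repeatability criterion over the maneuvers graded acceptable (grade 1).
#'
#' @param maneuvers List of [maneuver()] objects.
#' @param cfg A [default_config()].
#' @param policy A [grade_policy()].
#' @return A list of class `session_result`: `reports` (per maneuver),
#'   `grades`, `repeatability` (a `criterion_result`).
#' @export
assess_session <- function(maneuvers, cfg = default_config(),
                           policy = default_policy()) {
  if (!length(maneuvers)) stop_input("session has no maneuvers")
  reports <- lapply(maneuvers, assess_maneuver, cfg = cfg, policy = policy)
  grades <- vapply(reports, `[[`, integer(1), "grade")
  rep_res <- evaluate_repeatability(lapply(reports, `[[`, "indices"),
                                    acceptable = grades == 1L, cfg = cfg)
  structure(list(reports = reports, grades = grades,
                 repeatability = rep_res),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d maneuvers, grades: %s\n",
              length(x$grades), paste(x$grades, collapse = " ")))
  cat("  repeatability:", x$repeatability$outcome,
      if (!is.null(x$repeatability$reason)) paste0("(", x$repeatability$reason, ")") else "",
      "\n")
  invisible(x)
}

#' Sensitivity and specificity against expert labels
#'
#' Expert labels are 0 (reject) or 1 (acceptable); predictions may also be
#' 2 (needs expert review). Sensitivity is the fraction of expert-0 curves
#' predicted 0; specificity the fraction of expert-1 curves predicted 1.
#' Grade-2 predictions are counted separately and never enter a numerator,
#' so routing curves to expert review depresses both rates.
#'
#' @param predicted Integer vector of predicted grades in \{0, 1, 2\}.
#' @param expert Integer vector of expert grades in \{0, 1\}.
#' @return A list of class `confusion_stats`: `sensitivity`, `specificity`,
#'   `n_grade0`, `n_grade1`, `n_grade2`.
#' @export
score_against_labels <- function(predicted, expert) {
  if (length(predicted) != length(expert)) {
    stop_input("predicted and expert must have the same length")
  }
  if (!all(expert %in% c(0, 1))) stop_input("expert labels must be 0 or 1")
  if (!all(predicted %in% c(0, 1, 2))) {
    stop_input("predicted grades must be 0, 1 or 2")
  }
  n0 <- sum(expert == 0)
  n1 <- sum(expert == 1)
  structure(list(
    sensitivity = if (n0 == 0) NA_real_ else sum(predicted == 0 & expert == 0) / n0,
    specificity = if (n1 == 0) NA_real_ else sum(predicted == 1 & expert == 1) / n1,
    n_grade0 = sum(predicted == 0),
    n_grade1 = sum(predicted == 1),
    n_grade2 = sum(predicted == 2)),
    class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion_stats> sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  predicted grades: 0:%d  1:%d  2:%d\n",
              x$n_grade0, x$n_grade1, x$n_grade2))
  invisible(x)
}
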