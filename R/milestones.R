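#' Milestone configuration
#'
#' Two future reserve milestones are projected: the DOR milestone at POR
#' probability 0.5 (reserve score 50) and perimenopause. The perimenopause
#' probability corresponds conceptually to the lowest reserve score observed
#' in an ART population; that value is not published, so it is a required
#' configuration parameter with a documented default of 0.95 (score 5).
#' When a training cohort is available, [estimate_peri_probability()]
#' estimates it as the maximum predicted POR probability observed.
#'
#' @param p_score50 POR probability of the score-50 milestone (fixed 0.5 by
#'   definition of the score, but configurable).
#' @param p_peri POR probability defining perimenopause (default 0.95).
#' @return Object of class `milestone_config`.
#' @examples
#' milestone_config()
#' @export
milestone_config <- function(p_score50 = 0.5, p_peri = 0.95) {
  if (!(0 < p_score50 && p_score50 < p_peri && p_peri < 1))
    stop("need 0 < p_score50 < p_peri < 1", call. = FALSE)
  structure(list(p_score50 = p_score50, p_peri = p_peri),
            class = "milestone_config")
}

#' @export
print.milestone_config <- function(x, ...) {
  cat(sprintf("Milestones: score-50 at p = %g, perimenopause at p = %g\n",
              x$p_score50, x$p_peri))
  invisible(x)
}

#' Estimate the perimenopause probability from a cohort
#'
#' The highest model-predicted POR probability in the cohort — the
#' probability of the lowest reserve score observed.
#'
#' @param model fitted `por_fit`.
#' @param cohort cohort table.
#' @return A probability.
#' @export
estimate_peri_probability <- function(model, cohort) {
  cohort <- as_cohort(cohort)
  ok <- !is.na(cohort$age_years) & !is.na(cohort$amh_ng_ml)
  max(predict_por_probability(model, cohort[ok, , drop = FALSE]))
}

#' Age at which a reserve milestone is reached (fixed-interval projection)
#'
#' Under the fixed-interval hypothesis an individual's aging trajectory is
#' the population curve shifted horizontally, so the time to any future
#' reserve state is the horizontal distance along the population curve:
#' `chronological_age + endocrine_age(p_target) - endocrine_age(p_current)`.
#' If the target is already reached (`p_target <= p_current`) the returned
#' age lies at or before the chronological age and carries an
#' `already_reached` attribute rather than erroring.
#'
#' @param curve an `aging_curve`.
#' @param chronological_age current age in years.
#' @param p_current current predicted POR probability.
#' @param p_target milestone POR probability.
#' @return Age in years with attribute `already_reached` (logical).
#' @examples
#' predict_milestone_age(aging_curve(0.25, 41), 30,
#'                       p_current = 0.05, p_target = 0.5)  # about 41.78
#' @export
predict_milestone_age <- function(curve, chronological_age, p_current,
                                  p_target) {
  stopifnot(inherits(curve, "aging_curve"))
  age <- chronological_age +
    endocrine_age(curve, p_target) - endocrine_age(curve, p_current)
  structure(age, already_reached = p_target <= p_current)
}

#' Per-subject milestone report
#'
#' Composes the full individual pipeline: model-predicted POR probability,
#' reserve score and grade, endocrine age, and projected chronological ages
#' at the score-50 and perimenopause milestones. Flags are raised when a
#' milestone is already reached and when the subject sits on the young
#' high-reserve plateau (`p_current` below the curve's value at the lower
#' edge of its age domain), where projections are weakly identified.
#'
#' @param model fitted `por_fit`.
#' @param curve fitted (or constructed) `aging_curve`.
#' @param record single record: list or one-row data.frame with
#'   `age_years` and `amh_ng_ml`.
#' @param config a [milestone_config()].
#' @return Object of class `milestone_report`: `chronological_age`,
#'   `p_current`, `score_current`, `grade`, `endocrine_age`,
#'   `age_at_score50`, `age_at_perimenopause`, `flags` (character vector).
#' @examples
#' coh <- generate_mechanistic_cohort(n = 5000, seed = 1)
#' fit <- fit_por_model(coh)
#' crv <- fit_logistic_curve(dor_proportions_by_age(coh, fit))
#' milestone_report(fit, crv, list(age_years = 30, amh_ng_ml = 4.5))
#' @export
milestone_report <- function(model, curve, record,
                             config = milestone_config()) {
  stopifnot(inherits(curve, "aging_curve"), inherits(config, "milestone_config"))
  record <- as.data.frame(record)
  if (nrow(record) != 1)
    stop("milestone_report takes a single record; use milestone_batch for tables",
         call. = FALSE)
  p <- predict_por_probability(model, record)
  s <- score_from_probability(p)
  a <- record$age_years
  a50 <- predict_milestone_age(curve, a, p, config$p_score50)
  aperi <- predict_milestone_age(curve, a, p, config$p_peri)
  flags <- character(0)
  if (attr(a50, "already_reached")) flags <- c(flags, "score50_already_reached")
  if (attr(aperi, "already_reached")) flags <- c(flags, "perimenopause_already_reached")
  if (p < curve_probability(curve, curve$age_domain[1]))
    flags <- c(flags, "high_reserve_plateau")
  structure(list(chronological_age = a, p_current = p, score_current = s,
                 grade = grade_from_score(s), endocrine_age = endocrine_age(curve, p),
                 age_at_score50 = as.numeric(a50),
                 age_at_perimenopause = as.numeric(aperi),
                 flags = flags, config = config),
            class = "milestone_report")
}

#' @export
print.milestone_report <- function(x, ...) {
  # reported ages rounded to 0.1 y; stored values are unrounded
  cat(sprintf("Age %.1f y | POR probability %.3f | reserve score %.1f (%s)\n",
              x$chronological_age, x$p_current, x$score_current, x$grade))
  cat(sprintf("Endocrine age: %.1f y\n", round(x$endocrine_age, 1)))
  cat(sprintf("Projected age at score 50:      %.1f y\n",
              round(x$age_at_score50, 1)))
  cat(sprintf("Projected age at perimenopause: %.1f y\n",
              round(x$age_at_perimenopause, 1)))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Batch milestone reports
#'
#' One row per cohort record, with the fields of [milestone_report()] and
#' flags collapsed to a semicolon-separated string.
#'
#' @inheritParams milestone_report
#' @param cohort cohort table.
#' @return data.frame, one row per record with valid age and AMH.
#' @export
milestone_batch <- function(model, curve, cohort,
                            config = milestone_config()) {
  cohort <- as_cohort(cohort)
  ok <- !is.na(cohort$age_years) & !is.na(cohort$amh_ng_ml)
  cohort <- cohort[ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- milestone_report(model, curve, cohort[i, , drop = FALSE], config)
    data.frame(subject_id = cohort$subject_id[i],
               chronological_age = r$chronological_age,
               p_current = r$p_current, score_current = r$score_current,
               grade = r$grade, endocrine_age = r$endocrine_age,
               age_at_score50 = r$age_at_score50,
               age_at_perimenopause = r$age_at_perimenopause,
               flags = paste(r$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Serialize a milestone report as JSON
#'
#' Inputs are echoed; reported ages are rounded to 0.1 year as in the
#' on-screen report.
#'
#' @param report a `milestone_report`.
#' @param path file path.
#' @export
write_milestone_report <- function(report, path) {
  stopifnot(inherits(report, "milestone_report"))
  obj <- list(schema = "ovaclock/milestone-report/1",
              chronological_age = report$chronological_age,
              p_por = report$p_current,
              score = round(report$score_current, 1),
              grade = report$grade,
              endocrine_age = round(report$endocrine_age, 1),
              age_at_score50 = round(report$age_at_score50, 1),
              age_at_perimenopause = round(report$age_at_perimenopause, 1),
              flags = report$flags,
              p_score50 = report$config$p_score50,
              p_peri = report$config$p_peri)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
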