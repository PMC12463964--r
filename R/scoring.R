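#' Ovarian reserve score from POR probability
#'
#' The 0-100 ovarian reserve score is `(1 - p) * 100`, where `p` is the
#' predicted probability of poor ovarian response. The map is a strictly
#' decreasing bijection from \[0, 1\] to \[0, 100\]: higher score means
#' lower POR risk and better reserve. `p = 0.5` maps to score 50 (the
#' diminished-reserve milestone); `p = 0.15`, the predicted-DOR threshold,
#' maps to score 85.
#'
#' @param p POR probability vector, each in \[0, 1\].
#' @return Numeric score(s) in \[0, 100\].
#' @examples
#' score_from_probability(c(0, 0.15, 0.5, 1))
#' @export
score_from_probability <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p must be a probability in [0, 1]", call. = FALSE)
  (1 - p) * 100
}

#' Recover the POR probability from a reserve score
#'
#' Inverse of [score_from_probability()]: `p = 1 - score / 100`.
#'
#' @param score reserve score(s) in \[0, 100\].
#' @return POR probability vector.
#' @export
probability_from_score <- function(score) {
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 100))
    stop("score must lie in [0, 100]", call. = FALSE)
  1 - score / 100
}

#' Qualitative grade for a reserve score
#'
#' Default bands anchor on the two clinically meaningful probabilities:
#' the predicted-DOR classification threshold p = 0.15 (score 85) and the
#' DOR milestone p = 0.5 (score 50). Scores of 85 and above grade "good",
#' 50 to below 85 "adequate", below 50 "diminished". Band edges and labels
#' are configurable; upper band edges are inclusive from below
#' (score 85 is "good", score 50 is "adequate").
#'
#' @param score reserve score(s) in \[0, 100\].
#' @param thresholds increasing interior band edges (default `c(50, 85)`).
#' @param labels band labels, lowest first (default
#'   `c("diminished", "adequate", "good")`); length `length(thresholds) + 1`.
#' @return Character vector of grades.
#' @examples
#' grade_from_score(c(49.9, 50, 85))
#' @export
grade_from_score <- function(score, thresholds = c(50, 85),
                             labels = c("diminished", "adequate", "good")) {
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 100))
    stop("score must lie in [0, 100]", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (length(labels) != length(thresholds) + 1)
    stop("need one more label than thresholds", call. = FALSE)
  labels[findInterval(score, thresholds) + 1L]
}

#' Reserve score report for a POR probability
#'
#' Bundles probability, score and grade.
#'
#' @param p POR probability (scalar or vector).
#' @inheritParams grade_from_score
#' @return data.frame with columns `p_por`, `score`, `grade`.
#' @examples
#' reserve_score(0.12)
#' @export
reserve_score <- function(p, thresholds = c(50, 85),
                          labels = c("diminished", "adequate", "good")) {
  s <- score_from_probability(p)
  data.frame(p_por = as.numeric(p), score = s,
             grade = grade_from_score(s, thresholds, labels))
}
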