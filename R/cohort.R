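#' Cohort tables
#'
#' A cohort is a plain `data.frame` with one row per woman per cycle and the
#' columns `subject_id`, `age_years`, `amh_ng_ml`, `oocytes_retrieved`,
#' `por`, `cycle_day`. Only `age_years` and `amh_ng_ml` are mandatory for
#' prediction; fitting additionally needs an outcome, either a binary `por`
#' label or an oocyte count from which POR is derived (`oocytes_retrieved <
#' 5`, the clinical definition of poor ovarian response).
#'
#' @name cohort
NULL

cohort_columns <- c("subject_id", "age_years", "amh_ng_ml",
                    "oocytes_retrieved", "por", "cycle_day")

#' Coerce and validate a cohort table
#'
#' Fills in missing optional columns, derives the POR label from the oocyte
#' count where absent (fewer than five oocytes retrieved = POR), and checks
#' range invariants: `age_years` in \[15, 60\], `amh_ng_ml >= 0`. AMH values
#' of exactly zero are retained; no outlier exclusion is performed.
#'
#' @param x data.frame with at least `age_years` and `amh_ng_ml`.
#' @param derive_por derive `por` from `oocytes_retrieved` where `por` is
#'   missing (default `TRUE`).
#' @return A validated cohort `data.frame` with all six schema columns.
#' @examples
#' as_cohort(data.frame(age_years = 33, amh_ng_ml = 1.8, oocytes_retrieved = 4))$por
#' @export
as_cohort <- function(x, derive_por = TRUE) {
  x <- as.data.frame(x)
  if (!all(c("age_years", "amh_ng_ml") %in% names(x)))
    stop("cohort must have columns 'age_years' and 'amh_ng_ml'", call. = FALSE)
  if (is.null(x$subject_id)) x$subject_id <- sprintf("S%05d", seq_len(nrow(x)))
  for (col in c("oocytes_retrieved", "por", "cycle_day"))
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  x$age_years <- as.numeric(x$age_years)
  x$amh_ng_ml <- as.numeric(x$amh_ng_ml)
  x$por <- as_binary01(x$por)
  if (derive_por) {
    fill <- is.na(x$por) & !is.na(x$oocytes_retrieved)
    x$por[fill] <- as.numeric(x$oocytes_retrieved[fill] < 5)
  }
  bad_age <- !is.na(x$age_years) & (x$age_years < 15 | x$age_years > 60)
  if (any(bad_age))
    stop(sprintf("age_years outside [15, 60] in %d row(s), e.g. row %d",
                 sum(bad_age), which(bad_age)[1]), call. = FALSE)
  bad_amh <- !is.na(x$amh_ng_ml) & x$amh_ng_ml < 0
  if (any(bad_amh))
    stop(sprintf("negative amh_ng_ml in %d row(s), e.g. row %d",
                 sum(bad_amh), which(bad_amh)[1]), call. = FALSE)
  x[c(cohort_columns, setdiff(names(x), cohort_columns))]
}

as_binary01 <- function(v) {
  if (is.logical(v)) return(as.numeric(v))
  if (is.character(v)) {
    out <- rep(NA_real_, length(v))
    out[v %in% c("1", "TRUE", "true", "yes", "Yes")] <- 1
    out[v %in% c("0", "FALSE", "false", "no", "No")] <- 0
    out[is.na(v) | v == ""] <- NA_real_
    return(out)
  }
  v <- as.numeric(v)
  if (any(!is.na(v) & !v %in% c(0, 1)))
    stop("'por' must be binary (0/1)", call. = FALSE)
  v
}

# rows usable for fitting: complete predictors + outcome
fitting_rows <- function(cohort) {
  !is.na(cohort$age_years) & !is.na(cohort$amh_ng_ml) & !is.na(cohort$por)
}
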