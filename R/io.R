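#' Read a cohort CSV
#'
#' Schema: header `subject_id,age_years,amh_ng_ml,oocytes_retrieved,por,
#' cycle_day`, comma-separated UTF-8, missing values as empty fields. The
#' two predictor columns are mandatory in the header; extra columns are
#' kept with a warning. The POR label is derived from the oocyte count
#' (fewer than five oocytes) where absent. Row-level problems — blank or
#' unparseable age/AMH, out-of-range values — are collected and reported
#' with data line numbers; by default they abort the read, or with
#' `on_invalid = "drop"` the offending rows are dropped with a warning.
#'
#' AMH must arrive in ng/mL. Inputs measured in pmol/L are rejected unless
#' an explicit conversion factor is supplied (`amh_units = "pmol_l"`,
#' `pmol_to_ng_factor`, conventionally 0.14), to avoid silent unit errors.
#'
#' @param path CSV file path.
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @param amh_units `"ng_ml"` (default) or `"pmol_l"`.
#' @param pmol_to_ng_factor multiplicative factor applied when
#'   `amh_units = "pmol_l"`; required in that case.
#' @return Cohort data.frame (see [as_cohort()]).
#' @export
read_cohort_csv <- function(path, on_invalid = c("error", "drop"),
                            amh_units = c("ng_ml", "pmol_l"),
                            pmol_to_ng_factor = NULL) {
  on_invalid <- match.arg(on_invalid)
  amh_units <- match.arg(amh_units)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE,
                  na.strings = "")
  mandatory <- c("age_years", "amh_ng_ml")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop(sprintf("schema error: missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(raw), cohort_columns)
  if (length(extra))
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(v) suppressWarnings(as.numeric(v))
  age <- num(raw$age_years)
  amh <- num(raw$amh_ng_ml)
  if (amh_units == "pmol_l") {
    if (is.null(pmol_to_ng_factor))
      stop("AMH given in pmol/L: supply pmol_to_ng_factor explicitly (conventionally 0.14)",
           call. = FALSE)
    amh <- amh * pmol_to_ng_factor
  }
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad))
      problems <<- c(problems,
                     sprintf("line %d: %s", line_no[bad], what)[seq_len(min(sum(bad), 10))])
    bad
  }
  bad <- flag(is.na(age), "age_years missing or unparseable") |
    flag(is.na(amh), "amh_ng_ml missing or unparseable")
  bad <- bad | flag(!is.na(age) & (age < 15 | age > 60), "age_years outside [15, 60]")
  bad <- bad | flag(!is.na(amh) & amh < 0, "negative amh_ng_ml")
  if (length(problems)) {
    msg <- paste(problems, collapse = "\n  ")
    if (on_invalid == "error")
      stop(sprintf("invalid rows in %s:\n  %s", path, msg), call. = FALSE)
    warning(sprintf("dropping %d invalid row(s) in %s:\n  %s",
                    sum(bad), path, msg), call. = FALSE)
  }
  keep <- !bad
  cols <- list(
    age_years = age[keep],
    amh_ng_ml = amh[keep],
    oocytes_retrieved = if (is.null(raw$oocytes_retrieved)) NA_real_
      else num(raw$oocytes_retrieved)[keep],
    por = if (is.null(raw$por)) NA_real_ else raw$por[keep],
    cycle_day = if (is.null(raw$cycle_day)) NA_real_
      else num(raw$cycle_day)[keep])
  if (!is.null(raw$subject_id)) cols$subject_id <- raw$subject_id[keep]
  as_cohort(as.data.frame(cols))
}

#' Write a cohort CSV
#'
#' @param cohort cohort table.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  write.csv(cohort[cohort_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a run configuration YAML
#'
#' Flat-ish YAML with optional blocks `model`, `evaluation`, `curve`,
#' `milestones`, `synthetic`, `output_dir`. Missing blocks fall back to
#' package defaults; seeds must be explicit integers where given.
#'
#' @param path YAML file path.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$curve$tau) && !(cfg$curve$tau > 0 && cfg$curve$tau < 1))
    stop("config: curve tau must be in (0, 1)", call. = FALSE)
  cfg
}

#' Write a reproducibility manifest
#'
#' JSON record of the effective configuration, seeds, package and R
#' versions, sufficient to re-run the deterministic steps bit-for-bit.
#'
#' @param path output path.
#' @param command the command or function being recorded.
#' @param params named list of effective parameters (seeds included).
#' @export
write_manifest <- function(path, command, params = list()) {
  obj <- list(schema = "ovaclock/manifest/1",
              command = command,
              params = params,
              package_version = as.character(packageVersion("ovaclock")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
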