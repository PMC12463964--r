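#' Per-age predicted-DOR proportions
#'
#' Bins a cohort to integer years of age (floor) and, at each age, computes
#' the fraction of records whose model-predicted POR probability is at or
#' above the threshold `tau`. Predicted POR at `tau = 0.15` — the observed
#' POR incidence — defines "predicted DOR" for the population aging curve;
#' this deliberately differs from the 0.5 classification threshold used for
#' individual risk communication.
#'
#' @param cohort cohort table.
#' @param model fitted `por_fit`.
#' @param tau predicted-DOR probability threshold (default 0.15).
#' @param min_n minimum records per age row; sparser ages (the tails of the
#'   age range) are excluded and recorded in `attr(, "excluded")`.
#' @return data.frame of class `dor_by_age` with columns
#'   `age, n, n_dor, proportion`; attributes `tau`, `min_n`, `excluded`.
#' @examples
#' coh <- generate_mechanistic_cohort(n = 5000, seed = 1)
#' fit <- fit_por_model(coh)
#' head(dor_proportions_by_age(coh, fit))
#' @export
dor_proportions_by_age <- function(cohort, model, tau = 0.15, min_n = 20) {
  stopifnot(inherits(model, "por_fit"), tau >= 0, tau <= 1)
  cohort <- as_cohort(cohort)
  ok <- !is.na(cohort$age_years) & !is.na(cohort$amh_ng_ml)
  cohort <- cohort[ok, , drop = FALSE]
  if (nrow(cohort) == 0) stop("no records with age and AMH", call. = FALSE)
  p <- predict_por_probability(model, cohort)
  age <- floor(cohort$age_years)
  tab <- aggregate(list(n = rep(1L, length(age)), n_dor = as.integer(p >= tau)),
                   by = list(age = age), FUN = sum)
  tab$proportion <- tab$n_dor / tab$n
  keep <- tab$n >= min_n
  excluded <- tab$age[!keep]
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0)
    stop(sprintf("insufficient data: every age row has n < %d", min_n),
         call. = FALSE)
  rownames(tab) <- NULL
  structure(tab, tau = tau, min_n = min_n, excluded = excluded,
            class = c("dor_by_age", "data.frame"))
}

#' Assemble a per-age DOR table from counts
#'
#' Constructor for externally computed (or simulated) per-age DOR counts,
#' producing the same object [dor_proportions_by_age()] returns.
#'
#' @param age integer ages (years).
#' @param n records per age.
#' @param n_dor predicted-DOR records per age (`n_dor <= n`).
#' @param tau the probability threshold the counts were classified at.
#' @return A `dor_by_age` data.frame.
#' @examples
#' dor_table(25:30, n = rep(100, 6), n_dor = c(2, 3, 5, 6, 9, 14))
#' @export
dor_table <- function(age, n, n_dor, tau = 0.15) {
  stopifnot(length(age) == length(n), length(n) == length(n_dor),
            all(n_dor <= n), all(n_dor >= 0), all(n > 0))
  structure(data.frame(age = age, n = n, n_dor = n_dor,
                       proportion = n_dor / n),
            tau = tau, min_n = 0L, excluded = integer(0),
            class = c("dor_by_age", "data.frame"))
}

#' Fit the two-parameter logistic ovarian-aging curve
#'
#' Least-squares fit of `proportion ~ 1 / (1 + exp(-k * (age - x0)))` to a
#' per-age predicted-DOR table, on the proportion scale. Asymptotes are
#' fixed at 0 and 1 (two-parameter form). The fit is deterministic:
#' Levenberg-Marquardt from a fixed start (`k = 0.25`/yr, `x0` at the
#' interpolated first crossing of proportion 0.5) with tight tolerances.
#' `r_squared` is `1 - SSres/SStot` on the (optionally n-weighted)
#' proportion scale.
#'
#' @param table a `dor_by_age` table ([dor_proportions_by_age()] or
#'   [dor_table()]).
#' @param weighting `"none"` (default; plain r² readout) or `"by_n"`
#'   (weight each age row by its record count).
#' @return Object of class `aging_curve`: `k` (per year), `x0` (midpoint
#'   age, years), `r_squared`, `tau`, `age_domain`, `weighting`.
#' @examples
#' tab <- dor_table(25:55, rep(1000, 31),
#'                  round(1000 * plogis(0.3 * (25:55 - 40))))
#' fit_logistic_curve(tab)
#' @export
fit_logistic_curve <- function(table, weighting = c("none", "by_n")) {
  stopifnot(inherits(table, "dor_by_age"))
  weighting <- match.arg(weighting)
  if (nrow(table) < 4)
    stop("need at least 4 age rows to fit the curve", call. = FALSE)
  y <- table$proportion
  age <- table$age
  if (all(y < 0.5) || all(y > 0.5))
    warning("proportions do not straddle 0.5; midpoint is extrapolated",
            call. = FALSE)
  if (diff(range(y)) < 1e-12)
    warning("flat proportions: data are not sigmoidal-increasing, k -> 0",
            call. = FALSE)
  w <- if (weighting == "by_n") table$n else rep(1, nrow(table))
  start <- list(k = 0.25, x0 = start_midpoint(age, y))
  fit <- tryCatch(
    minpack.lm::nlsLM(proportion ~ plogis(k * (age - x0)),
                      data = as.data.frame(table)[c("age", "proportion")],
                      start = start, weights = w,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e)
      stop(sprintf("aging-curve fit failed to converge: %s; start was k=%g, x0=%g",
                   conditionMessage(e), start$k, start$x0), call. = FALSE))
  est <- coef(fit)
  if (est[["k"]] <= 0)
    warning("fitted k <= 0: data are not increasing in age", call. = FALSE)
  res <- y - plogis(est[["k"]] * (age - est[["x0"]]))
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * res^2) / sum(w * (y - ybar)^2)
  aging_curve(k = est[["k"]], x0 = est[["x0"]], r_squared = r2,
              tau = attr(table, "tau"), age_domain = range(age),
              weighting = weighting)
}

# fixed deterministic start: interpolated first upward crossing of 0.5
start_midpoint <- function(age, y) {
  above <- which(y >= 0.5)
  if (length(above) == 0 || above[1] == 1) return(median(age))
  i <- above[1]
  age[i - 1] + (0.5 - y[i - 1]) / (y[i] - y[i - 1]) * (age[i] - age[i - 1])
}

#' Construct an ovarian-aging curve object
#'
#' Direct constructor for a known two-parameter logistic curve
#' `P(age) = 1 / (1 + exp(-k * (age - x0)))`; [fit_logistic_curve()] uses
#' it for fitted curves.
#'
#' @param k steepness per year, positive for an increasing curve.
#' @param x0 midpoint age in years (`P(x0) = 0.5`).
#' @param r_squared goodness of fit, `NA` for analytic curves.
#' @param tau predicted-DOR threshold the curve refers to.
#' @param age_domain ages over which the curve is supported by data.
#' @param weighting fit weighting used, if any.
#' @return Object of class `aging_curve`.
#' @examples
#' aging_curve(k = 0.25, x0 = 41)
#' @export
aging_curve <- function(k, x0, r_squared = NA_real_, tau = 0.15,
                        age_domain = c(20, 45), weighting = "none") {
  stopifnot(is.finite(k), is.finite(x0), length(age_domain) == 2)
  structure(list(k = k, x0 = x0, r_squared = r_squared, tau = tau,
                 age_domain = as.numeric(age_domain), weighting = weighting),
            class = "aging_curve")
}

#' @export
print.aging_curve <- function(x, ...) {
  cat(sprintf("Ovarian-aging curve: P(age) = 1/(1+exp(-%.4g (age - %.4g)))\n",
              x$k, x$x0))
  cat(sprintf("  midpoint x0 = %.2f y, steepness k = %.4f /y", x$x0, x$k))
  if (is.finite(x$r_squared)) cat(sprintf(", r^2 = %.4f", x$r_squared))
  cat(sprintf("\n  predicted-DOR threshold tau = %g, age domain %g-%g y\n",
              x$tau, x$age_domain[1], x$age_domain[2]))
  invisible(x)
}

#' Evaluate the aging curve at an age
#'
#' @param curve an `aging_curve`.
#' @param age age(s) in years.
#' @return Predicted-DOR probability `1 / (1 + exp(-k * (age - x0)))`.
#' @examples
#' curve_probability(aging_curve(0.25, 41), c(34.06, 41))
#' @export
curve_probability <- function(curve, age) {
  stopifnot(inherits(curve, "aging_curve"))
  plogis(curve$k * (as.numeric(age) - curve$x0))
}

#' Endocrine age: invert the aging curve at a probability
#'
#' The endocrine age for a predicted POR probability `p` is the age at
#' which the population curve reaches `p`:
#' `x0 + log(p / (1 - p)) / k`. Probabilities are clamped to
#' \[1e-6, 1 - 1e-6\] before inversion (with a message), because women on
#' the young high-reserve plateau can present probabilities numerically
#' indistinguishable from 0.
#'
#' @param curve an `aging_curve`.
#' @param p POR probability vector.
#' @param clamp_eps clamping bound (default 1e-6).
#' @return Endocrine age(s) in years.
#' @examples
#' endocrine_age(aging_curve(0.25, 41), 0.15)  # about 34.06 y
#' @export
endocrine_age <- function(curve, p, clamp_eps = 1e-6) {
  stopifnot(inherits(curve, "aging_curve"))
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p must be a probability in [0, 1]", call. = FALSE)
  clamped <- p < clamp_eps | p > 1 - clamp_eps
  if (any(clamped)) {
    message(sprintf("clamped %d probability value(s) to [%g, %g] before inversion",
                    sum(clamped), clamp_eps, 1 - clamp_eps))
    p <- pmin(pmax(p, clamp_eps), 1 - clamp_eps)
  }
  curve$x0 + qlogis(p) / curve$k
}

#' Serialize / deserialize an aging curve as JSON
#'
#' @param curve an `aging_curve`.
#' @param path file path.
#' @return `read_aging_curve` returns an `aging_curve`.
#' @export
write_aging_curve <- function(curve, path) {
  stopifnot(inherits(curve, "aging_curve"))
  jsonlite::write_json(c(list(schema = "ovaclock/aging-curve/1"),
                         unclass(curve)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_aging_curve
#' @export
read_aging_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ovaclock/aging-curve/1"))
    stop("not an ovaclock aging-curve file", call. = FALSE)
  aging_curve(k = obj$k, x0 = obj$x0,
              r_squared = if (is.null(obj$r_squared)) NA_real_ else obj$r_squared,
              tau = obj$tau, age_domain = obj$age_domain,
              weighting = obj$weighting)
}
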