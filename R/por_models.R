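#' Model specification for POR prediction
#'
#' Three codings of the two predictors (chronological age and serum AMH) are
#' supported, mirroring the candidate specifications compared during model
#' development:
#'
#' * `model0` — categorical: age and AMH are cut into bins and entered as
#'   indicator columns (reference bin dropped). If no cut-points are given
#'   they default to quintiles of the training cohort.
#' * `model1` — continuous, untransformed: `(age, amh)`.
#' * `model2` — polynomial: quadratic in age, cubic in AMH, with all
#'   lower-order terms included: `(age, age^2, amh, amh^2, amh^3)`.
#'
#' Optional centering subtracts reference values (default age 35 y, AMH
#' 2 ng/mL) before taking powers; it conditions the cubic design without
#' changing fitted probabilities.
#'
#' @param name `"model0"`, `"model1"` or `"model2"`.
#' @param age_bins,amh_bins strictly increasing interior cut-points
#'   (`model0` only). `NULL` means "compute quintile cut-points at fit time".
#' @param center subtract `age_center`/`amh_center` before building
#'   polynomial terms.
#' @param age_center,amh_center centering references (years, ng/mL).
#' @return An object of class `por_model_spec`.
#' @examples
#' por_model_spec("model2")
#' por_model_spec("model0", age_bins = 35, amh_bins = 1.1)
#' @export
por_model_spec <- function(name = c("model2", "model1", "model0"),
                           age_bins = NULL, amh_bins = NULL,
                           center = FALSE, age_center = 35, amh_center = 2) {
  name <- match.arg(name)
  check_bins <- function(b, what) {
    if (is.null(b)) return(invisible())
    if (anyNA(b) || is.unsorted(b, strictly = TRUE))
      stop(sprintf("%s cut-points must be strictly increasing", what),
           call. = FALSE)
  }
  check_bins(age_bins, "age"); check_bins(amh_bins, "AMH")
  structure(list(name = name, age_bins = age_bins, amh_bins = amh_bins,
                 center = isTRUE(center), age_center = age_center,
                 amh_center = amh_center),
            class = "por_model_spec")
}

#' @export
print.por_model_spec <- function(x, ...) {
  cat("POR model spec:", x$name, "\n")
  if (x$name == "model0") {
    cat("  age cut-points:", fmt_bins(x$age_bins), "\n")
    cat("  AMH cut-points:", fmt_bins(x$amh_bins), "\n")
  }
  if (x$center)
    cat(sprintf("  centered at age %g y, AMH %g ng/mL\n",
                x$age_center, x$amh_center))
  invisible(x)
}

fmt_bins <- function(b) if (is.null(b)) "<quintiles at fit time>" else
  paste(signif(b, 4), collapse = ", ")

#' Build the design (feature) row(s) for a model specification
#'
#' Maps `(age, amh)` to the model's feature columns (no intercept). Column
#' order is fixed: `model1` gives `(age, amh)`; `model2` gives
#' `(age, age2, amh, amh2, amh3)`; `model0` gives indicator columns
#' `age_binK`, `amh_binK` for bins 2..k (first bin is the reference). Values
#' outside the `model0` bin range fall in the outermost bin; that is the
#' defined behaviour of interior cut-points, not an error.
#'
#' @param record one-row data.frame/list with `age_years` and `amh_ng_ml`,
#'   or a whole cohort table (vectorized).
#' @param spec a [por_model_spec()]. For `model0` the bins must be resolved
#'   (non-`NULL`); [fit_por_model()] resolves quintile defaults.
#' @return Numeric matrix, one row per record, named columns.
#' @examples
#' build_design(list(age_years = 30, amh_ng_ml = 2), por_model_spec("model2"))
#' @export
build_design <- function(record, spec) {
  stopifnot(inherits(spec, "por_model_spec"))
  record <- as.data.frame(record)
  age <- as.numeric(record$age_years)
  amh <- as.numeric(record$amh_ng_ml)
  if (length(age) == 0 || anyNA(age) || anyNA(amh))
    stop("invalid record: age_years and amh_ng_ml must be present and non-missing",
         call. = FALSE)
  if (spec$name == "model0") {
    if (is.null(spec$age_bins) || is.null(spec$amh_bins))
      stop("model0 bins are unresolved; fit the model or supply cut-points",
           call. = FALSE)
    return(cbind(bin_indicators(age, spec$age_bins, "age"),
                 bin_indicators(amh, spec$amh_bins, "amh")))
  }
  if (spec$center) {
    age <- age - spec$age_center
    amh <- amh - spec$amh_center
  }
  if (spec$name == "model1")
    return(cbind(age = age, amh = amh))
  cbind(age = age, age2 = age^2, amh = amh, amh2 = amh^2, amh3 = amh^3)
}

# indicator columns for bins 2..k (findInterval: value below first cut-point
# -> bin 1 = reference; above last -> outermost bin)
bin_indicators <- function(x, cuts, prefix) {
  idx <- findInterval(x, cuts) + 1L
  k <- length(cuts) + 1L
  m <- matrix(0, nrow = length(x), ncol = k - 1L,
              dimnames = list(NULL, paste0(prefix, "_bin", 2:k)))
  for (j in 2:k) m[, j - 1L] <- as.numeric(idx == j)
  m
}

#' Fit a POR logistic regression model
#'
#' Maximum-likelihood logistic regression of the POR outcome (fewer than
#' five oocytes retrieved) on the features of `spec`, fitted by iteratively
#' reweighted least squares. Records lacking predictors or outcome are
#' dropped; the POR label is derived from the oocyte count where absent.
#'
#' Quasi-complete separation is flagged (not silently returned): if any
#' coefficient exceeds 50 on the standardized scale (`|beta_j| * sd(x_j)`),
#' `converged` is set to `FALSE` with a warning.
#'
#' @param cohort cohort table (see [as_cohort()]).
#' @param spec a [por_model_spec()]; `model0` quintile bins are computed
#'   here from the training data when unspecified.
#' @param tol convergence tolerance on the IRLS deviance (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return Object of class `por_fit`: `spec` (with resolved bins), `beta`
#'   (named, intercept first), `n_fit`, `log_likelihood`,
#'   `null_log_likelihood`, `converged`.
#' @examples
#' coh <- generate_class_conditional_cohort(n = 600, seed = 1)
#' fit <- fit_por_model(coh, por_model_spec("model1"))
#' coef(fit)
#' @export
fit_por_model <- function(cohort, spec = por_model_spec("model2"),
                          tol = 1e-8, max_iter = 100) {
  cohort <- as_cohort(cohort)
  keep <- fitting_rows(cohort)
  cohort <- cohort[keep, , drop = FALSE]
  n <- nrow(cohort)
  if (n < 2) stop("no usable records (need predictors and outcome)", call. = FALSE)
  if (n < 50)
    warning(sprintf("only %d usable records; estimates will be unstable", n),
            call. = FALSE)
  y <- cohort$por
  if (length(unique(y)) < 2)
    stop("degenerate fit: outcome has a single class", call. = FALSE)
  if (spec$name == "model0") {
    if (is.null(spec$age_bins))
      spec$age_bins <- quintile_cuts(cohort$age_years, "age")
    if (is.null(spec$amh_bins))
      spec$amh_bins <- quintile_cuts(cohort$amh_ng_ml, "AMH")
  }
  X <- build_design(cohort, spec)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop(sprintf("degenerate design: zero-variance column(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
  Xi <- cbind("(Intercept)" = 1, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(Xi, y, family = binomial(),
            control = glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  std_beta <- abs(beta[-1]) * sds
  converged <- isTRUE(fit$converged)
  p <- clamp_prob(plogis(drop(Xi %*% beta)))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  # complete separation: coefficients diverge on the standardized scale AND
  # the likelihood approaches its unbounded supremum (perfect fit). The
  # second condition keeps heavy-tailed polynomial columns (whose sd is
  # large) from being mistaken for divergence.
  if (any(std_beta > 50) && ll / n > -1e-3) {
    converged <- FALSE
    warning("possible complete separation: diverging standardized coefficients; fit flagged as non-converged",
            call. = FALSE)
  }
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  structure(list(spec = spec, beta = beta, n_fit = n,
                 log_likelihood = ll, null_log_likelihood = ll0,
                 converged = converged),
            class = "por_fit")
}

quintile_cuts <- function(x, what) {
  cuts <- unique(quantile(x, probs = seq(0.2, 0.8, by = 0.2), names = FALSE))
  if (length(cuts) < 1)
    stop(sprintf("cannot form %s quintile bins: too few distinct values", what),
         call. = FALSE)
  cuts
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' @export
print.por_fit <- function(x, ...) {
  cat(sprintf("POR logistic model (%s), n = %d, logLik = %.3f, %s\n",
              x$spec$name, x$n_fit, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  print(signif(x$beta, 5))
  invisible(x)
}

#' @export
coef.por_fit <- function(object, ...) object$beta

#' @export
logLik.por_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$beta),
            nobs = object$n_fit, class = "logLik")
}

#' Predict POR probability for new records
#'
#' Inverse-logit of the fitted linear predictor. Deterministic given the
#' model and record; probabilities are clamped strictly inside (0, 1).
#'
#' @param model a `por_fit`.
#' @param record one record (list/one-row data.frame with `age_years`,
#'   `amh_ng_ml`) or a cohort table.
#' @param force predict even from a non-converged model (default `FALSE`).
#' @return Numeric vector of POR probabilities in (0, 1).
#' @examples
#' coh <- generate_class_conditional_cohort(n = 600, seed = 1)
#' fit <- fit_por_model(coh, por_model_spec("model1"))
#' predict_por_probability(fit, list(age_years = 38, amh_ng_ml = 0.8))
#' @export
predict_por_probability <- function(model, record, force = FALSE) {
  stopifnot(inherits(model, "por_fit"))
  if (!model$converged && !force)
    stop("model did not converge; pass force = TRUE to predict anyway",
         call. = FALSE)
  X <- build_design(record, model$spec)
  clamp_prob(plogis(drop(cbind(1, X) %*% model$beta)))
}

#' Serialize / deserialize a fitted POR model as JSON
#'
#' Library-agnostic schema (`ovaclock/por-model/1`): spec fields, ordered
#' coefficient vector, fit metadata.
#'
#' @param model a `por_fit`.
#' @param path file path.
#' @return `read_por_model` returns a `por_fit`.
#' @export
write_por_model <- function(model, path) {
  stopifnot(inherits(model, "por_fit"))
  obj <- list(schema = "ovaclock/por-model/1",
              spec = unclass(model$spec),
              beta = as.list(model$beta),
              n_fit = model$n_fit,
              log_likelihood = model$log_likelihood,
              null_log_likelihood = model$null_log_likelihood,
              converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_por_model
#' @export
read_por_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ovaclock/por-model/1"))
    stop("not an ovaclock POR model file", call. = FALSE)
  spec <- obj$spec
  spec$age_bins <- if (length(spec$age_bins)) as.numeric(spec$age_bins) else NULL
  spec$amh_bins <- if (length(spec$amh_bins)) as.numeric(spec$amh_bins) else NULL
  spec <- structure(spec, class = "por_model_spec")
  structure(list(spec = spec, beta = unlist(obj$beta), n_fit = obj$n_fit,
                 log_likelihood = obj$log_likelihood,
                 null_log_likelihood = obj$null_log_likelihood,
                 converged = obj$converged),
            class = "por_fit")
}
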