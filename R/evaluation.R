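#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' AUC computed as the probability that a randomly chosen case outranks a
#' randomly chosen control, with ties counting one half; equivalently the
#' midrank Mann-Whitney U statistic divided by `n1 * n0`. An optional
#' percentile bootstrap confidence interval resamples records with
#' replacement under a fixed seed.
#'
#' @param labels binary outcome vector (0/1 or logical).
#' @param probs predicted probabilities (any monotone score works; AUC is
#'   invariant to strictly increasing transforms).
#' @param ci compute a bootstrap CI (default `FALSE`).
#' @param B bootstrap resamples (default 2000).
#' @param seed bootstrap seed (default 20170101).
#' @param conf confidence level (default 0.95).
#' @return List of class `auc_estimate`: `auc`, and with `ci = TRUE` also
#'   `ci_lower`, `ci_upper`, `B`, `conf`.
#' @examples
#' compute_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc  # 0.75
#' @export
compute_auc <- function(labels, probs, ci = FALSE, B = 2000,
                        seed = 20170101, conf = 0.95) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(probs))
  check_two_classes(labels, "AUC")
  out <- list(auc = auc_point(labels, probs), n = length(labels))
  if (ci) {
    bs <- bootstrap_stat(labels, probs, auc_point, B = B, seed = seed)
    q <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    out$ci_lower <- unname(q[1]); out$ci_upper <- unname(q[2])
    out$B <- B; out$conf <- conf
  }
  structure(out, class = "auc_estimate")
}

auc_point <- function(labels, probs) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_classes <- function(labels, what) {
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop(sprintf("%s undefined: only one outcome class present", what),
         call. = FALSE)
}

# generic percentile bootstrap over (labels, probs) pairs; resamples that
# lose a class are redrawn (up to 10 tries), else NA
bootstrap_stat <- function(labels, probs, statistic, B, seed, ...) {
  n <- length(labels)
  with_seed(seed, vapply(seq_len(B), function(b) {
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2)
        return(statistic(labels[idx], probs[idx], ...))
    }
    NA_real_
  }, numeric(1)))
}

# run code under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC = %.4f", x$auc))
  if (!is.null(x$ci_lower))
    cat(sprintf(" (%g%% CI %.4f-%.4f, B = %d)",
                100 * x$conf, x$ci_lower, x$ci_upper, x$B))
  cat("\n")
  invisible(x)
}

#' Calibration table of predicted vs observed POR
#'
#' Bins records by predicted probability (equal-frequency quantile bins by
#' default, equal-width optional) and tabulates per-bin size, mean predicted
#' probability and observed event proportion. A second table restricted to
#' predictions at or below 0.25 is attached — the probability range where
#' most of the screened population sits — binned the same way.
#'
#' @param labels binary outcome vector.
#' @param probs predicted probabilities.
#' @param n_bins number of bins (default 10; reduced with a warning when
#'   there are fewer distinct break points or records).
#' @param method `"quantile"` (equal frequency) or `"width"` (equal width).
#' @return Object of class `calibration_table`: `$table` and `$zoom`
#'   data.frames with columns `bin, lower, upper, n, mean_pred, obs_prop`.
#' @examples
#' ct <- calibration_table(rep(0:1, each = 5), c(rep(0.1, 5), rep(0.9, 5)), n_bins = 2)
#' ct$table
#' @export
calibration_table <- function(labels, probs, n_bins = 10,
                              method = c("quantile", "width")) {
  labels <- as.numeric(labels)
  method <- match.arg(method)
  stopifnot(length(labels) == length(probs), n_bins >= 2)
  structure(list(table = calib_bins(labels, probs, n_bins, method),
                 zoom = {
                   sel <- probs <= 0.25
                   if (any(sel)) calib_bins(labels[sel], probs[sel], n_bins, method)
                   else NULL
                 },
                 n = length(labels), method = method),
            class = "calibration_table")
}

calib_bins <- function(labels, probs, n_bins, method) {
  n <- length(labels)
  if (n < n_bins) {
    warning(sprintf("fewer records (%d) than bins (%d); reducing bins", n, n_bins),
            call. = FALSE)
    n_bins <- max(1L, n)
  }
  breaks <- if (method == "quantile")
    unique(quantile(probs, probs = seq(0, 1, length.out = n_bins + 1),
                    names = FALSE))
  else seq(min(probs), max(probs), length.out = n_bins + 1)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + 1e-9)
  idx <- cut(probs, breaks, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(sort(unique(idx)), function(b) {
    in_bin <- idx == b
    data.frame(bin = b, lower = breaks[b], upper = breaks[b + 1],
               n = sum(in_bin), mean_pred = mean(probs[in_bin]),
               obs_prop = mean(labels[in_bin]))
  })
  do.call(rbind, rows)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration table (%s bins, n = %d)\n", x$method, x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot a calibration table
#'
#' Observed event proportion against mean predicted probability per bin,
#' with the ideal diagonal; optionally the 0-0.25 zoom panel.
#'
#' @param x a [calibration_table()].
#' @param zoom plot the restricted 0-0.25 table instead (default `FALSE`).
#' @param ... passed to [plot()].
#' @export
plot_calibration <- function(x, zoom = FALSE, ...) {
  stopifnot(inherits(x, "calibration_table"))
  tab <- if (zoom) x$zoom else x$table
  if (is.null(tab)) stop("no records at or below 0.25; zoom table is empty",
                         call. = FALSE)
  lim <- if (zoom) c(0, 0.25) else c(0, 1)
  plot(tab$mean_pred, tab$obs_prop, xlim = lim, ylim = lim,
       xlab = "Mean predicted POR probability",
       ylab = "Observed POR proportion", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::lines(tab$mean_pred, tab$obs_prop)
  invisible(x)
}

#' Continuous (category-free) net reclassification improvement
#'
#' NRI comparing a new risk model against a reference:
#' `[P(up | event) - P(down | event)] + [P(down | nonevent) - P(up | nonevent)]`,
#' where "up"/"down" means the new model moved the predicted risk up/down;
#' ties contribute zero. Ranges over \[-2, 2\]. Percentile bootstrap CI
#' under a fixed seed.
#'
#' @param labels binary outcome vector.
#' @param probs_reference,probs_new predicted risks under the two models.
#' @inheritParams compute_auc
#' @return List of class `nri_estimate`: `nri`, event/nonevent components,
#'   optional CI fields.
#' @examples
#' continuous_nri(c(1, 1, 0, 0), c(0.3, 0.3, 0.3, 0.3), c(0.4, 0.25, 0.2, 0.1))$nri
#' @export
continuous_nri <- function(labels, probs_reference, probs_new, ci = FALSE,
                           B = 2000, seed = 20170101, conf = 0.95) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(probs_reference),
            length(labels) == length(probs_new))
  check_two_classes(labels, "NRI")
  point <- nri_point(labels, probs_new - probs_reference)
  out <- list(nri = point$nri, nri_events = point$ev, nri_nonevents = point$ne,
              n = length(labels))
  if (ci) {
    d <- probs_new - probs_reference
    bs <- bootstrap_stat(labels, d, function(l, dd) nri_point(l, dd)$nri,
                         B = B, seed = seed)
    q <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    out$ci_lower <- unname(q[1]); out$ci_upper <- unname(q[2])
    out$B <- B; out$conf <- conf
  }
  structure(out, class = "nri_estimate")
}

nri_point <- function(labels, delta) {
  s <- sign(delta)
  ev <- mean(s[labels == 1])    # P(up|event) - P(down|event)
  ne <- -mean(s[labels == 0])   # P(down|nonevent) - P(up|nonevent)
  list(nri = ev + ne, ev = ev, ne = ne)
}

#' @export
print.nri_estimate <- function(x, ...) {
  cat(sprintf("Continuous NRI = %.4f (events %.4f, nonevents %.4f)",
              x$nri, x$nri_events, x$nri_nonevents))
  if (!is.null(x$ci_lower))
    cat(sprintf("; %g%% CI %.4f-%.4f", 100 * x$conf, x$ci_lower, x$ci_upper))
  cat("\n")
  invisible(x)
}

#' Age-stratified AMH summaries
#'
#' Median and quartiles of AMH within age strata. Default strata follow the
#' conventional reproductive-age grouping: `<=30`, `>30-<=40`, `>40` years
#' (the boundary age 30 belongs to the youngest stratum). Percentiles use
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param cohort cohort table.
#' @param breaks interior age cut-points, right-closed (default `c(30, 40)`).
#' @return data.frame with `stratum, n, median, q25, q75`; empty strata get
#'   `n = 0` and `NA` percentiles.
#' @examples
#' coh <- generate_mechanistic_cohort(n = 2000, seed = 1)
#' amh_summary_by_age_strata(coh)
#' @export
amh_summary_by_age_strata <- function(cohort, breaks = c(30, 40)) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  edges <- c(-Inf, breaks, Inf)
  labs <- stratum_labels(breaks)
  idx <- cut(cohort$age_years, edges, labels = FALSE, right = TRUE)
  out <- lapply(seq_along(labs), function(s) {
    amh <- cohort$amh_ng_ml[!is.na(idx) & idx == s & !is.na(cohort$amh_ng_ml)]
    if (length(amh) == 0)
      data.frame(stratum = labs[s], n = 0L, median = NA_real_,
                 q25 = NA_real_, q75 = NA_real_)
    else
      data.frame(stratum = labs[s], n = length(amh),
                 median = median(amh),
                 q25 = quantile(amh, 0.25, names = FALSE, type = 7),
                 q75 = quantile(amh, 0.75, names = FALSE, type = 7))
  })
  do.call(rbind, out)
}

stratum_labels <- function(breaks) {
  k <- length(breaks)
  c(sprintf("<=%g", breaks[1]),
    if (k > 1) sprintf(">%g-<=%g", breaks[-k], breaks[-1]),
    sprintf(">%g", breaks[k]))
}

#' Full discrimination / calibration / reclassification report
#'
#' Convenience wrapper bundling [compute_auc()] (with CI),
#' [calibration_table()] and — when a reference risk vector is supplied —
#' [continuous_nri()] into one object.
#'
#' @param labels binary outcome vector.
#' @param probs predicted risks of the model under evaluation.
#' @param probs_reference optional reference-model risks for NRI.
#' @param n_bins calibration bins.
#' @inheritParams compute_auc
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(labels, probs, probs_reference = NULL,
                              n_bins = 10, B = 2000, seed = 20170101,
                              conf = 0.95) {
  out <- list(auc = compute_auc(labels, probs, ci = TRUE, B = B, seed = seed,
                                conf = conf),
              calibration = calibration_table(labels, probs, n_bins = n_bins),
              nri = if (!is.null(probs_reference))
                continuous_nri(labels, probs_reference, probs, ci = TRUE,
                               B = B, seed = seed, conf = conf),
              n = length(labels))
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$auc)
  if (!is.null(x$nri)) print(x$nri)
  print(x$calibration)
  invisible(x)
}
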