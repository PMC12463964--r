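# Independent oracles, deliberately naive: these re-derive expected values
# by enumeration or exhaustive search and must never call the code paths
# they check.

# AUC by brute-force enumeration of all case-control pairs (ties = 1/2)
brute_auc <- function(labels, probs) {
  cases <- probs[labels == 1]
  controls <- probs[labels == 0]
  total <- 0
  for (u in cases)
    for (v in controls)
      total <- total + (u > v) + 0.5 * (u == v)
  total / (length(cases) * length(controls))
}

# continuous NRI straight from its definition
enum_nri <- function(labels, p_ref, p_new) {
  d <- p_new - p_ref
  ev <- mean(d[labels == 1] > 0) - mean(d[labels == 1] < 0)
  ne <- mean(d[labels == 0] < 0) - mean(d[labels == 0] > 0)
  ev + ne
}

# Bernoulli log-likelihood of a logistic model on a design with intercept
toy_loglik <- function(beta, X, y) {
  eta <- drop(cbind(1, X) %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# coordinate-wise grid-zoom maximum-likelihood search, independent of
# IRLS. The raw intercept/age ridge is nearly collinear, so the search
# runs on a standardized copy of the design (an exact affine
# reparametrization) where cyclic coordinate ascent on the smooth concave
# log-likelihood converges to the global maximizer; the result is mapped
# back to the original scale in closed form.
grid_mle <- function(X, y, cycles = 400) {
  xbar <- colMeans(X)
  s <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, xbar), 2, s, "/")
  p <- ncol(X) + 1
  beta <- rep(0, p)
  line_zoom <- function(j, center) {
    half <- 50
    for (round in 1:6) {
      grid <- seq(center - half, center + half, length.out = 41)
      lls <- vapply(grid, function(v) {
        b <- beta; b[j] <- v; toy_loglik(b, Z, y)
      }, numeric(1))
      center <- grid[which.max(lls)]
      half <- 2 * (grid[2] - grid[1])
    }
    center
  }
  for (cy in seq_len(cycles))
    for (j in seq_len(p))
      beta[j] <- line_zoom(j, beta[j])
  slopes <- beta[-1] / s
  c(beta[1] - sum(slopes * xbar), slopes)
}

# 6-record toy cohort used across fitting tests; the tied covariate pair
# with opposite labels (rows 2-3) guarantees the classes overlap so the
# MLE is finite
toy_cohort <- function() {
  data.frame(
    age_years = c(30, 34, 34, 38, 40, 42),
    amh_ng_ml = c(4, 2, 2, 1.2, 0.8, 0.5),
    por = c(0, 0, 1, 1, 0, 1))
}

# noiseless logistic curve table (exact proportions, no sampling)
exact_sigmoid_table <- function(k, x0, ages = 25:55) {
  p <- plogis(k * (ages - x0))
  dor_table(ages, n = rep(1000L, length(ages)), n_dor = 1000 * p)
}
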