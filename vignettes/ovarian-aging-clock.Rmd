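---
title: "Methods: an ovarian-aging clock from AMH and age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an ovarian-aging clock from AMH and age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovaclock)
```

## The problem

Serum anti-Müllerian hormone (AMH, ng/mL) is secreted by growing ovarian
follicles and tracks the size of the remaining follicle pool. Together with
chronological age it predicts *poor ovarian response* (POR) — retrieval of
fewer than five oocytes after controlled ovarian stimulation — which is the
measurable, binary proxy for diminished ovarian reserve available in ART
(assisted reproductive technology) cohorts. `ovaclock` turns that
prediction into three progressively more interpretable quantities:

1. a 0–100 **ovarian reserve score**, `(1 − p) × 100`, where `p` is the
   predicted POR probability;
2. an **endocrine age**, obtained by locating `p` on a population
   ovarian-aging curve;
3. projected **chronological ages at future reserve milestones** (score 50,
   and a perimenopause level), under the fixed-interval hypothesis.

## POR models

The outcome is modeled by logistic regression,
`logit P(POR) = β₀ + βᵀx`, with three codings of `(age, AMH)`:

* **model0** (categorical): indicator columns for bins of age and of AMH,
  reference bin dropped. The historical cut-points behind this coding are
  not available, so the default bins are training-cohort quintiles,
  overridable via `por_model_spec()`. Out-of-range values fall in the
  outermost bin by construction.
* **model1** (continuous): `(age, amh)` untransformed.
* **model2** (polynomial): quadratic in age, cubic in AMH, with all
  lower-order terms — `(age, age², amh, amh², amh³)`. "Quadratic" and
  "cubic" denote polynomial degree; hierarchical polynomials (all lower
  powers included) are the standard construction and keep the model
  invariant to predictor shifts.

Fitting is maximum likelihood by iteratively reweighted least squares
(tolerance 1e-8 on the deviance, 100 iterations). Optional centering
(age − 35, AMH − 2) conditions the cubic design; fitted probabilities are
invariant to it (verified to 1e-6 in the tests). AMH = 0 is a legitimate
value and is retained; predictors are never log-transformed in the model
itself. Complete separation is detected — diverging coefficients on the
standardized scale *and* a log-likelihood at its unbounded supremum — and
flagged as non-convergence rather than returned silently. The
standardized-coefficient check alone would misfire here: the cubic AMH
column of a heavy-tailed AMH distribution has an enormous standard
deviation, so large standardized coefficients arise in perfectly healthy
fits.

Predictions are clamped to the open interval (0, 1) at 1e-12 so that
downstream log-odds arithmetic is always defined.

## Evaluation

* **AUC** is the Mann–Whitney concordance probability (midranks; ties count
  one half). Confidence intervals are percentile bootstrap, B = 2000,
  default seed 20170101, because the analytic variance is not needed
  anywhere downstream.
* **Calibration** uses 10 equal-frequency bins of predicted probability by
  default (equal-width optional), with a companion table restricted to
  predictions ≤ 0.25 — the range where the large majority of a screening
  population sits, and where miscalibration matters most clinically.
* **NRI** is the category-free (continuous) variant: published comparisons
  of these models do not state risk categories, and the continuous form
  needs no invented cut-offs. A categorical variant would require
  user-supplied thresholds; events and non-events components are reported
  separately so either direction of movement can be inspected.
* **Percentile convention** everywhere: linear interpolation between order
  statistics (R type 7).

## The aging curve and endocrine age

For the population curve, "predicted DOR" is defined as predicted POR
probability ≥ τ = 0.15 — the observed POR incidence — *not* the 0.5
classification threshold used for individual risk communication. Records
are binned to integer years (floor); age rows with fewer than `min_n = 20`
records are excluded (the tails of the age range are sparse and noisy).
The proportion of predicted DOR against age is then fitted with a
two-parameter logistic

`P(age) = 1 / (1 + exp(−k (age − x₀)))`

by Levenberg–Marquardt least squares on the proportion scale, unweighted by
default (matching a plain r² readout; by-n weighting is available). The
two-parameter form fixes the asymptotes at 0 and 1. The start is
deterministic — `k = 0.25`/yr and `x₀` at the interpolated first crossing
of proportion 0.5 — with tolerances of 1e-10, so refits are bit-for-bit
reproducible.

The **endocrine age** of a probability `p` is the curve's inverse,
`x₀ + log(p/(1−p))/k`. Probabilities are clamped to [1e-6, 1 − 1e-6] (with
a message) before inversion: young women with high reserve sit on the flat
plateau of the curve where `p` is numerically near zero and the inverse is
unbounded.

## Milestones and the fixed-interval hypothesis

The fixed-interval hypothesis asserts that individual aging trajectories
share the population curve's shape and differ only by a horizontal offset.
The time for an individual to move from her current probability to a
target is then the horizontal distance along the population curve:

`age_at_target = age + [endocrine_age(p_target) − endocrine_age(p_current)]`.

Two milestones are reported: score 50 (`p = 0.5`, the DOR milestone by
definition of the score) and perimenopause. The perimenopause probability
corresponds to the lowest reserve score observed in an ART population; no
published value exists, so it is a configurable parameter defaulting to
`p = 0.95` (score 5), and `estimate_peri_probability()` can estimate it
from a training cohort as the maximum predicted probability. Milestones
already passed return past ages with an `already_reached` flag rather than
erroring — a deployed tool must still answer for low-reserve users. A
`high_reserve_plateau` flag marks subjects whose probability lies below
the curve's value at the lower edge of its fitted age domain; for them the
projections are weakly identified and can substantially precede the truth.
Reports round ages to 0.1 year for display; stored values are unrounded.

Grade bands for the score are likewise anchored on the only two meaningful
published thresholds — score 85 (`p = 0.15`, the predicted-DOR cut-off)
and score 50 — giving "good" (≥ 85), "adequate" (50–85), "diminished"
(< 50), all configurable.

## Synthetic cohorts

No patient-level data are distributed; the generators emulate the
*printed summary structure* of a large ART cohort and expose every
parameter.

**Class-conditional generator.** POR ~ Bernoulli(2224/15241 ≈ 0.146);
given the label, AMH is lognormal matched to the published class medians
and quartiles — POR-negative 3.14 (1.70, 5.40) ng/mL, POR-positive 0.67
(0.34, 1.31) — via `meanlog = log(median)`,
`sdlog = (log q75 − log q25)/1.349`, and age is truncated normal on
[20, 45] matched to 32 (29, 35) and 36 (32, 40) years. Only median and IQR
are published, so only they are matched; the printed quartiles are not
exactly log-symmetric, so the lognormal reproduces the median exactly and
the quartile *ratio*, leaving individual quartiles within ~4%.

**Mechanistic generator.** A forward model with a known truth, for
closed-loop parameter-recovery studies: age ~ truncated Normal(32, 6²) on
[20, 45] (a typical ART age mix); `log AMH ~ Normal(log m(age), σ²)` with
σ = 0.55 — smaller than the ~0.86 marginal class log-sd, which includes
the age effect — and `log m(age)` piecewise-linear between knots at ages
26, 35, 42 (flat outside); and
`logit P(POR) = a₀ + 0.12·age − 1.7·log(AMH + 0.01)`, with `a₀` solved at
generation time so expected prevalence hits the target. The knot ages are
the typical (median) ages of the `≤30`, `>30–≤40`, `>40` strata under the
default age distribution. The slopes are tunable shape parameters chosen
to land in a realistic discrimination regime; they are not published
quantities. The `+0.01` keeps AMH = 0 admissible.

The published stratum medians (3.65 / 2.26 / 0.98 ng/mL) are treated as
**calibration targets**, not directly as knot values: mixing over ages
within a stratum under log-scale noise drags the realized stratum median
several percent below the knot value, so the generator solves for knot
log-medians by a deterministic fixed point on the analytic mixture CDF
such that the realized stratum medians equal the targets
(`calibrate = TRUE`; raw-knot mode available). The generator also returns
its exact true DOR-by-age curve (`true_dor_curve()`), which has a closed
form because the threshold event is a normal tail at fixed age.

**Stimulation-day decline.** Relative to a cycle-day-2 draw, mean AMH
declines of 17.4% (day 6) and 49.7% (hCG trigger day) are applied either
exactly (mean mode) or with per-subject Beta-distributed decline fractions
of the configured mean and sd 0.2 (mean-preserving). Only the two mean
declines are published; the heterogeneity sd is a model parameter, set
large enough to matter at the hCG-day mean while keeping the Beta
well-defined at the day-6 mean (sd < 0.38). Note one subtlety: a *pure
mean* decline is a rank-preserving rescaling only for a score monotone in
AMH alone; once age enters the linear predictor, rescaling AMH is not a
monotone transform of the combined score, so exact AUC invariance is
stated — and tested — for AMH-only monotone scores. Between-subject
heterogeneity is the mechanism that strictly degrades discrimination; the
published severity of the hCG-day collapse is not reproducible without the
unpublished variance structure, so the package checks direction and
monotonicity, not magnitude.

## What the tests do and do not show

The test and acceptance runs use cohorts of 10,000–30,000 records for
calibration and recovery checks, 15,000 for held-out discrimination, and
1,000 subjects per integer age over ages 25–55 for the curve fit; these
sizes put Monte-Carlo error well inside the stated tolerances while
keeping a full run in seconds. Passing them shows internal consistency —
the pipeline recovers what the generators put in (e.g. the aging-curve
midpoint to within a year at n = 30,000) and reproduces the printed
summary statistics it was calibrated to. It does *not* validate the
clinical model on real women: the generators draw AMH and age
independently within outcome class (class-conditional mode), assume a
single lognormal per class, one cycle per woman, and no assay or
platform variability. Real cohorts violate all of these in some measure.

## Known limitations

* The fixed-interval hypothesis is supported by cross-sectional data only;
  individual-level longitudinal validation does not exist. Milestone
  projections are hypothesis-generating.
* For high-reserve young women the plateau makes projections weakly
  identified (flagged, not suppressed).
* The categorical model's historical cut-points are quintile stand-ins.
* The perimenopause probability default (0.95) is a documented convention,
  not a published value.
* Endpoints are ART endpoints; generalization beyond age ~40 in community
  populations is not established.
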