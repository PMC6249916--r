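---
title: "Texture-based prognostic scoring for solitary HCC: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based prognostic scoring for solitary HCC: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radsurv` implements a complete radiomics-to-prognosis workflow for
solitary hepatocellular carcinoma (HCC): quantitative texture features are
extracted from the tumor region of one CT slice, compressed into a scalar
**rad-score** by lasso-penalized logistic regression on the five-year
outcome, dichotomized at a survival-optimal cutpoint, and evaluated as a
prognostic factor with Kaplan–Meier curves, Cox models, point-scaled
nomograms, Harrell's C-index, bootstrap calibration and intraclass
correlation (ICC) reproducibility. Because no patient cohort is
distributed with the package, a synthetic cohort generator with a planted
texture–survival association makes every stage testable end to end.

This vignette documents the models, the tunable parameters, and the
design decisions taken where the methodology left genuine choices open.

## The texture feature vector

Each lesion is one grayscale slice plus a binary mask (`roi_image`). The
in-mask intensities are rebinned into `Ng` equal-width gray levels
spanning the in-mask minimum to maximum (`quantize_roi`; default
`Ng = 32`). Equal-width binning over the observed range is the common
convention when no calibrated intensity scale (e.g. a fixed HU window) is
assumed; its known cost is sensitivity of the level map to the extremes,
which the reproducibility module measures rather than hides.

The default catalog (`feature_catalog()`) holds exactly **110 features**:

* **14 first-order** descriptors of the raw in-mask intensities: mean,
  median, min, max, range, population variance, SD, skewness, excess
  kurtosis, 10th/90th percentiles, interquartile range, and histogram
  entropy (base 2) and uniformity over the `Ng` bins.
* **13 Haralick features** of the symmetric, normalized gray-level
  co-occurrence matrix (GLCM) at distance 1, reported separately for the
  four offsets (0,1), (1,0), (1,1), (1,−1) — 52 features. Pairs count
  only when both pixels are in-mask; there is no padding.
* **11 run-length features** of the gray-level run-length matrix (GLRLM)
  along the same four directions — 44 features. Runs are broken by the
  mask boundary.

Numerical conventions: all logarithms are base 2 with `0·log 0 ≡ 0`;
skewness and kurtosis of a constant region are defined as 0; a
co-occurrence matrix with no valid pair is flagged degenerate and its
features take neutral values (correlation 1, contrast 0, energy 1); the
second information measure of correlation is clamped to [0, 1]. These
conventions keep all 110 features finite on single-pixel, constant and
checkerboard regions, which the test suite asserts. Reporting the four
directions separately (rather than averaging) is what brings the catalog
to exactly 110 with the families above; the composition is recorded in a
catalog sidecar written next to every feature table.

Three-dimensional inputs are reduced to the slice with the largest mask
area — the largest cross-sectional area of the tumor — before
extraction. PNG and NIfTI readers are provided; DICOM input is not
supported (no DICOM reader is available to the package), so DICOM series
should be converted to NIfTI upstream.

## The rad-score

The logistic outcome is the **event status at five years** (60 months):
patients censored before 60 months are excluded from score fitting,
because their five-year status is unknowable; everyone else is labelled
by whether the event occurred within 60 months. `fit_radscore`
standardizes the feature matrix (the per-feature means and SDs are frozen
into the model), fits the L1-penalized logistic path with `glmnet`, and
selects the penalty by 10-fold cross-validated AUC with folds stratified
by outcome under a recorded seed. Both selection rules are available:
the CV-maximum (`"min"`) and the more conservative one-standard-error
rule (`"one_se"`, the default). At full-cohort sizes the one-SE rule
typically retains a handful of features; on small cohorts it can retain
none, in which case the CV-minimum rule is the practical choice (the
package's own small-cohort tests do exactly that).

The score is `orientation × (intercept + Σ βj zj)` with default
orientation −1, so **lower scores indicate the aggressive phenotype**
(higher five-year event risk). The orientation is stored in the model and
any affine re-expression of the score is deliberately out of scope: with
the default orientation the score's sign convention matches a workflow in
which the low-score group carries the risk.

## Cutpoint, survival analysis, validation discipline

`find_cutpoint` scans every midpoint between adjacent distinct score
values whose split keeps at least `min_group_fraction` (default 10%) of
patients on each side, computes the two-group log-rank chi-square at each
candidate, and returns the maximizer — the maximally selected log-rank
approach popularized by the X-tile tool. Ties break toward the lower
candidate. No multiple-testing correction is applied to the reported
p-value, matching the common practice of quoting the raw optimal split;
the full scan is returned so users can apply one (e.g.
Miller–Siegmund) themselves.

Kaplan–Meier estimation, the log-rank test, Cox regression (Breslow tie
handling by default, Efron by flag, Wald intervals) and Harrell's
C-index are thin, contract-checked wrappers over the `survival` package;
the log-rank statistic used inside the cutpoint scan is a vectorized
life-table computation asserted equal to `survival::survdiff` in the
tests. Multivariate Cox models are assembled by the conventional
two-stage rule: covariates with univariate p < 0.05 enter (configurable).
A warning — not an error — fires when events are fewer than ten per
covariate.

`run_pipeline` enforces the validation discipline: feature
standardization, the penalty, the coefficients and the cutoff are
computed on the training split only and frozen before any validation
data are touched. The returned provenance records the training ids, and
the test suite asserts that corrupting every validation outcome and
image changes no frozen parameter.

## Nomograms, calibration, model comparison

`build_nomogram` re-expresses a Cox fit on the familiar 0–100 point
scale: each covariate's points are its risk contribution `βj·xj` anchored
at the lowest-risk end of its observed range, scaled so the widest
contribution spans exactly 0–100. Total points are then a strictly
increasing affine transform of the linear predictor, and the
total-points axis maps to predicted survival at the requested horizons
(default 36 and 60 months) through the Breslow baseline,
`S(t|x) = S0(t)^exp(lp)`.

`bootstrap_calibration` refits the model on `B` bootstrap resamples
(default 50) and averages the resample predictions on the original
cohort — a simple bootstrap smoothing. Patients are grouped by
predicted-survival quantiles (default quartiles; the group count is a
free choice and quartiles keep every group populated at cohort sizes in
the hundreds), observed survival per group is Kaplan–Meier at the
horizon, and agreement is tested with a Hosmer–Lemeshow-style grouped
chi-square on observed-versus-expected events with `groups − 2` degrees
of freedom. Groups with nobody at risk at the horizon are merged with a
neighbor and flagged.

`compare_models` reports Harrell's C with bootstrap percentile 95%
intervals (default `B = 200`) for any set of risk scores — the
rad-score, nomogram linear predictors, and ordinal staging systems (TNM,
BCLC, JIS, HKLC) consumed as-is from input columns; stage assignment
from raw clinical data is out of scope.

## Reproducibility: ICC(2,1)

`icc_2_1` implements the two-way random-effects, single-measure,
absolute-agreement intraclass correlation from the standard ANOVA mean
squares, with the published reliability grades (< 0.40 poor, 0.41–0.59
fair, 0.60–0.74 good, 0.75–1.00 excellent; boundaries resolve as 0.40 →
poor, 0.60 → good, 0.75 → excellent). Tables with zero total variance
are flagged degenerate (ICC defined as 1), and features with zero
between-subject variance are flagged rather than silently scored.

Human readers are unavailable to a software package, so
`perturbed_rereads` emulates a re-delineation: membership of the
`radius`-pixel boundary band is redrawn from a spatially smoothed random
field, so the perturbed contour differs by contiguous bulges and notches
the way two freehand outlines do. This is a surrogate for — not a claim
about — radiologist variability; it stresses the same boundary
sensitivity. Under the defaults (1-pixel band, 20% expected band
turnover) the median ICC across the 110 features on 60 synthetic lesions
is ≈ 0.76, inside the 0.71–0.95 inter-observer band reported for real
readers, and degrades monotonically as the band widens.

## The synthetic cohort generator

`simulation_config()` defines the study conditions; the defaults emulate
a 319-patient solitary-HCC resection cohort randomly split 212/107 into
training and validation:

* **Latent aggressiveness class** (two classes, equiprobable). Class 2 is
  the aggressive phenotype.
* **Images**: a jittered elliptical tumor mask (at least 10% of a 64×64
  slice) filled with a moving-average-smoothed Gaussian random field.
  The class sets the field's mean intensity (100 vs 110), spatial
  correlation length (1 vs 5 px) and variance (1); a correlation length
  of zero with zero variance gives a constant region. Per-patient
  heterogeneity (`texture_jitter`: mean SD 3, log-scale SDs 0.5/0.3)
  makes lesions within a class vary continuously, as real lesions do —
  without it, between-subject variance is so small that reproducibility
  coefficients are meaningless. The surrounding parenchyma is 1.5 noise-SD
  darker with matched noise, a modest soft-tissue contrast; an earlier
  20%-darker background made the equal-width quantization collapse under
  1-pixel mask jitter, which no plausible re-read of a real lesion does.
  The planted class contrast is deliberately strong (the pipeline
  recovers the class with AUC ≈ 0.99): the end-to-end checks exercise
  information flow and leakage control, and a strong plant keeps them
  from doubling as underpowered power studies. Power behaviour is tested
  separately at module level with controlled effect sizes.
* **Survival**: Weibull event times per class (TTR shape 1.1, scales
  90/45 months; OS shape 1.3, scales 130/65 — a scale ratio of 2, median
  OS near 70 months for the indolent class and five-year survival around
  70%, consistent with a resected solitary-HCC population). Recurrence
  observed after death is truncated at the death time; because the
  endpoints are drawn independently, aggressive-class patients are
  disproportionately censored-by-death before recurring, which dilutes
  the planted recurrence separation relative to overall survival — the
  recurrence endpoint is genuinely harder here, as in real cohorts.
  Censoring is
  uniform on `[0, t_max]` with `t_max` solved per class so the expected
  censoring probability equals `censor_rate` (default 0.3) — simple and
  analytically checkable. The generator exposes censoring controls but
  does not attempt to match any particular follow-up mean/SD pair.
* **Covariates**: binary pathology markers (size class, vascular
  invasion, encapsulation) from class-conditional Bernoulli draws through
  a logistic link; laboratory values (GGT, AFP) from class-shifted
  log-normals; staging ordinals (TNM, BCLC, JIS, HKLC) from a
  class-shifted latent normal cut into four grades. The association
  directions mirror the aggressive phenotype (larger size, more invasion,
  less encapsulation, higher labs, higher stage) without claiming any
  particular magnitude. Setting every association to zero decouples
  covariates from the class, which the tests verify.

Identical configurations generate bitwise-identical cohorts; the
generator seeds a private RNG stream and restores the caller's state.

**What passing tests do and do not show.** The generator produces
stationary Gaussian textures, elliptical masks, a single slice, and
exactly two latent phenotypes. Real CT shows nonstationary enhancement,
irregular margins, scanner/protocol effects and a continuum of biology.
Green tests therefore demonstrate that the machinery is correct — the
statistics match their oracles, training-derived parameters are frozen,
a planted signal flows through to validation — not that any particular
clinical effect size will be observed on real patients.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline on
319-patient cohorts with 64×64 images (about 6–20 s per cohort depending
on the stages), the brute-force texture oracles on 100 random ≤ 8×8
masked images, lasso recovery on 50 replicates of a 400×50 design,
permutation nulls with 500 permutations, and Cox recovery at n = 1000 to
2000 — sizes at which the Monte-Carlo bounds asserted in the tests are
comfortably stable on a single CPU. Cox fits converge to a gradient
tolerance of 1e-10 (up to 100 Newton–Raphson iterations); monotone
likelihoods surface as errors naming the covariate; cutpoint ties break
toward the lower candidate; the lasso path stops at `λ_max/100`, below
which CV-AUC never selects in this regime.

## Known limitations

* No wavelet/filtered, shape, or 3-D texture families; no scanner
  harmonization.
* DICOM is not read directly.
* The five-year-outcome exclusion of early-censored patients discards
  information a time-to-event selection (e.g. penalized Cox) would keep;
  the logistic formulation is retained by design.
* The cutpoint p-value is the raw maximally selected statistic.
* Competing risks, time-varying covariates and stratified models are out
  of scope.
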