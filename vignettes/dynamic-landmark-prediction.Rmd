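---
title: "Dynamic landmark prediction: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic landmark prediction: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlpred)
```

## 1. The problem

Risk prediction tools in routine use are *static*: one Cox model is fit at
baseline and reused forever, with whatever covariate values are current
simply plugged into the old coefficients. For a progressive condition like
type 2 diabetes, this discards two kinds of information that accumulate
after baseline: the fact that the patient has remained disease-free to the
present visit, and the *trajectory* of their biomarkers (fasting plasma
glucose, HbA1c). `dlpred` implements the dynamic landmark alternative —
refitting the model at pre-specified landmark times $t_0$ among survivors,
with change-from-baseline biomarker covariates — and the machinery needed to
decide whether it is worth the added complexity.

## 2. Models and estimands

**Static model.** $P(T_i > \tau \mid Z_i) = \exp\{-\Lambda_0(\tau)
e^{\beta' Z_i}\}$, fit once by Cox partial likelihood on all subjects;
$\Lambda_0$ is the Breslow estimator. When used at a later visit, the
baseline lab values in $Z_i$ are replaced by the current labs but the
coefficients, baseline hazard and (crucially) the unconditional estimand
are unchanged. This mirrors current practice and is the package's default
static comparator (`predict_static_at_landmark`). The algebraically
conditioned variant $\exp\{-(\hat\Lambda_0(\tau) - \hat\Lambda_0(t_0))
e^{\hat\beta' Z_i}\}$ is exposed via `conditional = TRUE` but is *not* the
default, because it is not what a static tool reports to patients.

**Dynamic landmark model.** $P(T_i > \tau \mid T_i > t_0, Z_i(t_0)) =
\exp\{-\Lambda_0(\tau \mid t_0) e^{\alpha' Z_i(t_0)}\}$, refit on the risk
set $\{X_i > t_0\}$ for each $t_0$ (default 0, 1, 2, 3 years), with
$\tau = t_0 + t$ and horizon $t = 2$ years. A separate coefficient vector
is estimated at each landmark (no pooling across $t_0$).

**Landmark covariates.** The frame at $t_0$ carries baseline categoricals,
baseline labs, and the change from baseline to the last measurement at or
before $t_0$ (last observation carried forward, no staleness limit — on an
annual/semi-annual visit grid values are at most a year old). Baseline and
change jointly encode the current value, so current labs do not enter as a
third copy; this keeps the design full rank. At $t_0 = 0$ the change
columns are identically zero; they are dropped (and recorded in the fit),
which makes the baseline landmark fit *exactly* the static model — a
structural identity the tests assert metric-by-metric.

**Risk-set conventions.** Subjects with an event or censoring at or before
$t_0$ are excluded with a logged reason, as are subjects missing a baseline
lab (the generator reproduces a ~0.4% missing-HbA1c fraction to exercise
this path). Landmark fits use all residual follow-up after $t_0$; an
administrative truncation at $\tau$ (van Houwelingen-style) was considered
and not adopted as the default because the conditional-hazard model is the
estimand — truncation would only discard events.

## 3. Fitting: numerical choices

Partial-likelihood maximization is delegated to `survival::coxph.fit`
(Newton–Raphson, convergence tolerance 1e-9, 100 iterations) with **Efron
tie handling** by default. Ties are not a corner case here: onset is
detected at scheduled visits, so event times are heavily tied by
construction. Covariates are centered internally; the stored Breslow
baseline hazard refers to the centering point and all predictions are
invariant to it. Fits with non-finite coefficients, exploding standard
errors or |coef| > 25 are rejected with an error naming the covariate
(monotone likelihood / separation), and constant design columns are dropped
and flagged rather than silently estimated. Predictions beyond the last
event time clamp $\hat\Lambda_0$ at its final value and set an
`extrapolated` attribute. The fitter's correctness is anchored to an
independent oracle: a dense grid search of the explicit partial likelihood
on a printed five-subject fixture, to 1e-3.

## 4. Accuracy metrics

All metrics consume predicted *survival* probabilities; "higher risk"
always means lower $\hat p$, converted in exactly one place.

* **IPCW weights.** $\hat G$, the Kaplan–Meier curve of the censoring
  distribution (event indicator flipped), is estimated within the
  evaluation stratum (arm). Events in $(t_0, \tau]$ get weight
  $\hat G(t_0)/\hat G(X_i)$, survivors past $\tau$ get
  $\hat G(t_0)/\hat G(\tau)$, subjects censored inside the window get 0.
  With no censoring every weight is 1 and each metric reduces exactly to
  its unweighted empirical counterpart (tested by exhaustive enumeration on
  ≤12-subject fixtures).
* **AUC(τ, t₀):** weighted case–control pair proportion with ties counted
  one half.
* **Brier(τ, t₀):** weighted mean of $(I(T>\tau) - \hat p)^2$.
* **Hosmer–Lemeshow (survival extension):** five strata by quintiles of
  predicted risk; observed stratum event rates by IPCW; expected rates as
  mean predicted risk; statistic $\sum_g n_g (O_g - \bar E_g)^2 /
  (\bar E_g(1-\bar E_g))$ with $n_g$ the effective (total-weight) stratum
  size, referred to $\chi^2_{g-1}$. The published account names the test
  without printing a formula; this D'Agostino–Nam-style variance is the
  single biggest formula-level judgment call in the package and is
  deliberately isolated in one function. Degenerate strata are skipped with
  a warning and the degrees of freedom reduced.
* **NRI (category-free):** among events, the weighted percentage whose
  dynamic risk is strictly higher (correct direction) vs strictly lower
  than their static risk; likewise among non-events; combined as
  $(up_e - down_e) - (up_{ne} - down_{ne})$. Exact prediction ties are
  excluded from both directions and reported separately, so components sum
  to ≤ 100 within each group.

## 5. Evaluation protocol

Each metric is cross-validated: 2/3 of subjects train, 1/3 test, repeated
`cv_reps` times (default 100) and averaged; test splits that lack cases or
controls are skipped with a warning, never imputed. Confidence intervals
for the dynamic-minus-static difference come from subject-level bootstrap
resampling within arm (default 500 resamples) wrapping the *entire* CV
procedure — the alternative reading (bootstrapping test-set metrics around
fixed fits) was rejected because the refit is part of the estimator.
Inside each bootstrap resample the CV rep count drops to `cv_reps_boot`
(default 10): the per-resample estimand is a mean over splits, so this
trades Monte-Carlo noise for a 10× cost reduction without bias. CIs are
percentile intervals; p-values come from the bootstrap distribution's
position relative to zero.

## 6. The synthetic cohort generator

The generator emulates the structure of a diabetes-prevention-trial cohort
(placebo and metformin arms) so that every downstream stage is testable
without the restricted source data:

* **Baseline.** Categorical covariates (age group, gender, BMI group,
  smoking, race/ethnicity) drawn independently from published marginal
  frequencies, renormalized to sum to 1 (the source table's counts are
  internally inconsistent at the unit level; only marginals are available,
  so no correlation structure is attempted). Labs are truncated normal at
  zero: glucose ~ N(107.35, 7.84²) mg/dL, HbA1c ~ N(5.91, 0.51²)%.
* **Biomarker paths.** Gaussian random walk on the visit grid with
  subject-specific drift: glucose +1 mg/dL/yr (increment SD 4 mg/dL/√yr,
  between-subject drift SD 1.5), HbA1c +0.02%/yr (SDs 0.15, 0.04), floored
  at physiological minima. These magnitudes reflect the slow pre-diabetic
  progression seen in untreated high-risk adults; they were chosen once and
  are not tuned to test outcomes.
* **Event times.** Proportional hazards on the *current* (piecewise-
  constant) lab values: $\lambda(t) = \lambda_0 \cdot m_{\text{arm}} \cdot
  \exp\{m(t)[\beta_g (g(t) - 107.35) + \beta_h (h(t) - 5.91)]\}$ with
  defaults $\lambda_0 = 0.08$/yr, $\beta_g = \log 1.08$ per mg/dL,
  $\beta_h = \log 1.5$ per %, metformin multiplier 0.65, and
  $m(t) = 1 + \text{tv\_slope}\cdot t \equiv 1$ by default. Inverse-
  transform sampling is exact because the hazard is piecewise constant.
  Defaults give ≈18% (placebo) and ≈12% (metformin) event fractions by
  year 2, matching the published cohort.
* **Detection and censoring.** Onset is detected at the first lab visit at
  or after the latent time (visits at 0, 0.5, then annually through year
  8); diabetes onset is interval-detected, not simulated mechanistically
  from glucose thresholds — the hazard model drives onset. Censoring is
  min(administrative end ~ U(4.6, 8.35), exponential dropout at 2%/yr),
  snapped down to the last attended contact on a quarterly grid (trials of
  this design have quarterly non-lab contacts). The resulting reverse-
  Kaplan–Meier median follow-up is 6.25 years against a target of 6.11:
  snapping makes achievable medians multiples of 0.25, so the test accepts
  one grid step. Dropout is independent of covariates, a deliberate
  strengthening of the usual conditional-independence censoring assumption.
* **Misspecification scenario.** `misspec_cohort_config()` sets
  `tv_slope = 0.5` with stronger biomarker effects: the biomarker effect
  grows with time, violating proportional hazards for any baseline-only
  model. Under this world the dynamic model's cross-validated Brier score
  beats the static model's at late landmarks in nearly every replicate;
  under the correctly specified world (no drift, so baseline labs remain
  the true covariates) the two models' CV AUCs agree to within 0.02 on
  average. Both behaviors are asserted in the acceptance suite.

**What a green test does and does not establish.** The generator's
covariates are independent, its censoring is covariate-free, its biomarker
noise is Gaussian, and onset depends on labs only — real cohorts satisfy
none of these. Green simulation tests establish that the estimators do what
they claim under a known data-generating process (recovery, calibration,
proper-score behavior, the misspecification contrast), not that the
published cohort's numerical results are reproduced; those require the
restricted data.

## 7. Known limitations

* No time-varying-coefficient fits, splines, penalization, super-landmark
  pooling, or joint longitudinal–survival models (explicit non-goals).
* The HL survival extension and the NRI's handling of within-window
  censoring are under-specified in the literature the package follows; the
  IPCW choices made here are documented above and switchable in code.
* YAML configuration requires an optional package; JSON is the supported
  format in offline environments.
* Bootstrap p-values are percentile-based and become degenerate (reported
  as ≥ the resolution of `bootstrap_reps`) for very large effects.
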