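# dlpred — dynamic landmark prediction for diabetes-free survival

`dlpred` implements and evaluates **dynamic landmark Cox models** for
predicting incident type 2 diabetes from longitudinal biomarker
measurements (fasting plasma glucose and HbA1c), and compares them against
the **static** single-model approach that dominates risk-prediction
practice. It is aimed at biostatisticians studying dynamic risk prediction
who do not have access to restricted trial data: a synthetic cohort
generator with known ground truth makes the entire pipeline testable
end-to-end.

## The models

For subject *i* with covariates *Z<sub>i</sub>*, event time *T<sub>i</sub>*,
censoring time *C<sub>i</sub>*, observed time
*X<sub>i</sub>* = min(*T<sub>i</sub>*, *C<sub>i</sub>*) and indicator
*D<sub>i</sub>*, the **static model** is a single baseline Cox model

> P(T<sub>i</sub> > τ | Z<sub>i</sub>) = exp{ −Λ₀(τ) exp(β′Z<sub>i</sub>) }

fit once by partial likelihood, with Λ₀ the Breslow baseline cumulative
hazard. In practice this one model is reused at later visits by plugging in
current lab values — without conditioning on having remained diabetes-free.

The **dynamic landmark model** is refit at each landmark time *t₀* (default
0, 1, 2, 3 years) among subjects still event-free at *t₀*:

> P(T<sub>i</sub> > τ | T<sub>i</sub> > t₀, Z<sub>i</sub>(t₀)) =
> exp{ −Λ₀(τ|t₀) exp(α′Z<sub>i</sub>(t₀)) }

where τ = t₀ + t (horizon t = 2 years) and Z<sub>i</sub>(t₀) adds the
**change in glucose and HbA1c from baseline to t₀** to the baseline
covariates. At t₀ = 0 the two models coincide.

Accuracy at each (τ, t₀) is estimated with censoring-robust
inverse-probability-of-censoring-weighted (IPCW) estimators —
AUC(τ, t₀) = P(p̂<sub>i</sub> < p̂<sub>j</sub> | t₀ < T<sub>i</sub> ≤ τ,
T<sub>j</sub> > τ) for discrimination and the Brier score
E[(I(T > τ) − p̂)² | T > t₀] for calibration — plus a survival extension of
the Hosmer–Lemeshow test and the category-free net reclassification
improvement (NRI), all wrapped in repeated 2/3–1/3 train/test splitting and
subject-level bootstrap CIs.

## Worked example

```r
library(dlpred)

arms <- list(
  placebo   = generate_cohort(cohort_config(n_subjects = 1027, seed = 2)),
  metformin = generate_cohort(cohort_config(n_subjects = 1030,
                                            arm = "metformin", seed = 3))
)
cfg <- protocol_config(cv_reps = 20, bootstrap_reps = 0, seed = 4)
report <- run_full_study(arms, cfg)
report$metrics
```

```
         arm t0 tau metric static dynamic difference
1    placebo  0   2    auc  0.684   0.684   0.000000
2    placebo  0   2  brier  0.142   0.142   0.000000
3    placebo  1   3    auc  0.739   0.738  -0.000615
4    placebo  1   3  brier  0.145   0.135  -0.009451
5    placebo  2   4    auc  0.747   0.743  -0.003337
6    placebo  2   4  brier  0.165   0.131  -0.034504
7    placebo  3   5    auc  0.782   0.776  -0.006631
8    placebo  3   5  brier  0.191   0.140  -0.051578
9  metformin  0   2    auc  0.603   0.603   0.000000
10 metformin  0   2  brier  0.117   0.117   0.000000
11 metformin  1   3    auc  0.660   0.655  -0.005351
12 metformin  1   3  brier  0.118   0.114  -0.003875
13 metformin  2   4    auc  0.741   0.728  -0.012882
14 metformin  2   4  brier  0.127   0.107  -0.019490
15 metformin  3   5    auc  0.719   0.707  -0.012766
16 metformin  3   5  brier  0.156   0.110  -0.046296
```

Reading this: at t₀ = 0 the static and dynamic entries are identical (same
model). At later landmarks the cross-validated **Brier score of the dynamic
model is consistently lower** (better calibrated absolute risks — e.g.
0.140 vs 0.191 at t₀ = 3 in the placebo arm) because the static model
neither conditions on survival to t₀ nor sees biomarker changes, while
**AUC differences are small** (both models rank subjects similarly). The
same pattern shows in `report$hl`: the static model's Hosmer–Lemeshow
statistic explodes at late landmarks (e.g. 69.6 vs 9.8 at t₀ = 3, placebo)
while the dynamic model stays near its null. This mirrors the behavior
reported for these methods on real diabetes-prevention trial data, where
the restricted cohort gave dynamic-model AUCs of 0.645–0.752 and
significantly better Brier scores at all post-baseline landmarks.

`write_report(report, "out/")` writes `report.json`, `report.csv` and a
two-panel AUC/Brier figure. A command-line surface is also installed:

```sh
Rscript inst/cli/dlpred simulate --config cfg.json --seed 7 --out data/
Rscript inst/cli/dlpred run-study --config proto.json \
    --cohort data/subjects.csv --labs data/labs.csv --out out/
```

## Scope notes

The restricted trial data behind the published application (available only
under an NIDDK data-use agreement) are not bundled; the synthetic generator
emulates the cohort's structure (covariate frequencies, lab distributions,
visit schedule, interval-detected onset, ~6.1-year median follow-up). Only
placebo and metformin arms are modeled; joint longitudinal–survival models,
time-varying-coefficient fits, splines and regularization are out of scope.
See `vignettes/dynamic-landmark-prediction.Rmd` for the full methods
account.
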