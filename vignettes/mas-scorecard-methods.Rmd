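---
title: "Methods: diagnostic models and a weight-of-evidence scorecard for MAS secondary to SLE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic models and a weight-of-evidence scorecard for MAS secondary to SLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Macrophage activation syndrome (MAS) is a hyperinflammatory complication of
systemic lupus erythematosus (SLE) with substantial mortality. Its hallmarks
— fever, cytopenias, hyperferritinaemia, liver injury, coagulopathy — also
occur in active lupus, so early discrimination between "SLE flare" and "MAS
secondary to SLE" from routine admission data is genuinely hard. `mascard`
implements a complete diagnostic-modelling workflow over the thirteen
predictors that best discriminate the two conditions: maximum temperature,
duration of fever, serum sodium, triglycerides, HDL cholesterol, LDH,
ferritin, CRP, fibrinogen, prothrombin time, TNF-α, and the two composite
indicators pancytopenia and liver damage.

Because no patient-level dataset is publicly available, the package is
driven by a synthetic-cohort generator whose defaults emulate a balanced
94 + 94 case–control design. Everything downstream — imputation, feature
selection, classifiers, the scorecard — is exercised and tested against
that generator.

## The synthetic cohort generator

`default_feature_specs()` declares, for each predictor, a class-conditional
sampling distribution, clinical units, an adult reference interval, and a
missingness rate. The design principles:

* **Distribution families.** Heavy-tailed analytes (ferritin,
  triglycerides, LDH, CRP, TNF-α, fever duration) are log-normal; the rest
  are normal; the composites are Bernoulli. This matches the skew of real
  laboratory panels.
* **Directions.** The MAS class runs higher in ferritin, temperature, fever
  duration, CRP, LDH, triglycerides and PT, lower in fibrinogen, HDL,
  sodium and TNF-α, and has higher prevalence of pancytopenia and liver
  damage. MAS locations respect the established clinical anchors: the
  ferritin median (2313 µg/L) sits above the 1242.25 µg/L level reported to
  discriminate MAS, the triglyceride median (3.62 mmol/L) above the
  3 mmol/L hypertriglyceridaemia criterion, and fibrinogen (2.09 g/L)
  approaches the hypofibrinogenaemia range.
* **Effect sizes.** Every continuous predictor carries the same
  standardized separation, 1.8 pooled-SD units (log scale for the skewed
  analytes). A uniform separation keeps each of the thirteen predictors
  individually useful to the optimal classifier, which is what makes
  "recover the planted panel" a meaningful benchmark for the selection
  stage; jointly the panel is strongly but not perfectly separable, the
  regime a high-performing clinical discriminator actually operates in.
  The Bernoulli composites use prevalence contrasts (6% → 72% and
  10% → 74%) near the ceiling of what a binary indicator can express.
* **Correlation.** Features are conditionally independent given the class
  by default. A `severity_rho` knob induces an equicorrelated latent
  "inflammatory severity" factor across the continuous predictors
  (marginals unchanged) for users who want to study selection and
  calibration under redundancy; it is off by default because correlated
  informative features make "which features are truly informative"
  ill-posed for the recovery benchmark.
* **Missingness** is injected completely at random, per feature, at rates
  between 0 and 12% — spanning both imputation tiers (below 5%:
  mean/plurality; 5–20%: iterative random forest). MNAR/MAR mechanisms are
  out of scope.
* **Nuisance features.** Twenty standard-normal noise features, identical
  in both classes, exercise both selection stages.
* **Mortality bookkeeping.** The per-group death indicator fixes the
  margin (`round(rate × n)`, 15/94 in the MAS group, 0/94 in SLE) and
  randomizes positions, so the baseline table is emulated exactly rather
  than only in expectation.

What passing tests on this generator do **not** show: robustness to
informative missingness, batch effects between assays, label noise from
imperfect reference criteria, or feature distributions that differ in shape
(not just location) between classes. Real cohorts have all four.

## Preprocessing

* **Tiered imputation** (`impute_cohort()`): features missing below 5% get
  plurality (binary) or mean (continuous) fills; between 5% and 20%, an
  iterative random-forest imputer (100 trees, at most 10 sweeps,
  seed-controlled, built on `ranger`) repeatedly re-predicts each gap from
  all other features until the filled values change by less than 0.1% of a
  feature SD. Features at or above 20% missingness are refused by name:
  dropping data is a caller's decision, never silent. Observed entries are
  never altered; if there are no covariates to learn from, the mean/mode
  fill stands.
* **Shift audit** (`audit_shift()`): per imputed feature, a two-sample
  Mann-Whitney U test of observed values against the completed vector. The
  comparison populations are a design choice (the source procedure names
  only the test); observed-vs-completed is the most conservative pairing
  available without refitting.
* **Range flags** (`derive_range_flags()`): a ternary companion per
  continuous feature — 1 above the reference interval, −1 below, 0 inside,
  bounds inclusive (clinical reference intervals are conventionally
  inclusive). Flags depend only on the raw value and the interval.
* **Outliers** (`flag_outliers_iqr()`): Tukey fences at `k = 1.5` IQR;
  flagged entries are winsorized to the fences by default (removal would
  discard the extreme-but-real values that characterize MAS). Winsorization
  matters quantitatively: without it the heavy-tailed analytes lose much of
  their standardized separation to tail variance.
* **Standardization** (`zscore_fit()` / `zscore_apply()`): per-feature mean
  and *population* standard deviation (divisor n, so two points `{2, 4}`
  map exactly to `{−1, 1}`), fitted on training data only and reused
  unchanged on test and external cohorts.

Pipeline order: impute → (flags) → winsorize → split → Z-score. Whether
outlier processing precedes or follows standardization is an open choice;
clipping on the raw scale keeps the fences in clinical units.

## Two-stage feature selection

Stage one removes redundancy: `pearson_filter()` drops, from every pair
with |r| ≥ 0.8, the member less correlated with the diagnosis;
`vif_filter()` then iteratively removes the largest variance inflation
factor until all VIF < 10. Both cutoffs are conventional screening values
and are exposed as arguments. Ties everywhere resolve by ascending feature
name, so selection is invariant to column order.

Stage two is the LASSO (`lasso_select()`): an L1-penalized logistic path
with 5-fold class-stratified cross-validation on binomial deviance,
**repeated over five independent fold assignments** and averaged — at
n ≈ 190 a single CV curve is noisy enough that the chosen penalty visibly
wanders between seeds, occasionally dropping a genuinely informative
feature (curve minimum too early) or admitting a burst of noise features
(too late); averaging the curves stabilizes both. The penalty is then
chosen by the **one-standard-error rule** by default. We ship both rules
(`rule = "min"` restores the deviance minimum), but the minimum rule
demonstrably over-selects here: with twenty nuisance features at n = 188
it admits four to six of them on average across seeds, the textbook
overselection behaviour of `lambda.min`, while the 1-SE rule keeps false
inclusions at or below three in the overwhelming majority of seeds without
sacrificing recovery of the planted panel. The composite features
(`make_composites()`) implement pancytopenia as a three-lineage conjunction
(haemoglobin, platelets and white cells all below their lower limits) and
liver damage as a transaminase disjunction (ALT or AST above its upper
limit); the composite definitions are an assumption of this package, stated
prominently because the originating description names the composites
without defining them.

The pipeline's default candidate set excludes the range-flag features:
flags are deterministic transforms of the raw predictors, and including
near-duplicates of the signal makes planted-truth recovery ill-defined.
`range_flags = TRUE` restores them.

## Classifiers and evaluation

Four reference families (`model_spec()`): L2-penalized logistic regression
(`glmnet`, ridge always active), random forest (`ranger`), RBF-kernel SVM
(`e1071`, probabilities from its internal 5-fold Platt-scaled sigmoid —
a held-out calibration), and gradient boosting (`xgboost`). Small default
grids (penalty strengths; mtry; cost; learning rate × depth) are tuned by
exhaustive grid search with stratified 5-fold inner CV on pooled AUC, ties
to the first configuration, and refit on the full training split.

Validation follows the small-sample playbook: a stratified 80/20
train/test split, leave-one-out on the training split (n model fits, one
pooled prediction vector), and a drifted external cohort scored with the
training Z-score model after excluding patients with any missing value
(per-patient exclusion). Feature screening runs on the full internal cohort
before the split — the screening-then-model order of the original design —
so the test split guards the classifiers' fit, not the screening.

Metrics: rank-based ROC-AUC (the Mann-Whitney normalization, ties counted
half) and F-beta at threshold 0.5, with

$$F_\beta = (1+\beta^2)\,\frac{P \cdot R}{\beta^2 P + R},$$

reported for β = 1 and β = 2. F2 weights recall four times precision:
missing a MAS case is the expensive error.

## The diagnostic scorecard

1. **Binning.** Continuous features are discretized by ChiMerge
   (`chimerge_bin()`): 20 quantile pre-bins, then repeated merging of the
   adjacent pair with the *smallest* chi-square statistic while that pair's
   p ≥ 0.05 or more than 8 bins remain, stopping at 3 bins or when every
   adjacent pair differs significantly. Quantile pre-bins are the default
   (robust to skewed analytes); equal-width is available. One published
   description of this step reads as "merge the pair with p < 0.05 and the
   highest chi-square", which would delete exactly the cut points that
   separate the classes; we implement standard ChiMerge and provide the
   literal variant behind `merge = "most_different"` for comparison.
   Binary features keep their two categories.
2. **Weight of evidence.** Per bin, `WOE = ln(SLE\% / MAS\%)` — the log
   ratio of the bin's share of all SLE patients to its share of all MAS
   patients. Zero cells receive +0.5 additive smoothing and shares are
   renormalized, so every WOE is finite.
3. **Model.** A logistic regression on the WOE-encoded features with a
   ridge penalty of 0.1 (`fit_woe_lr()`). The penalty is a stability
   choice with a scale rationale: the score map below can only represent
   log-odds in roughly ±9 on a 0–100 point scale, and on a strongly
   separable training cohort a near-unpenalized fit pushes the linear
   predictor far beyond that, saturating the scale and degrading the
   density estimates downstream. Cross-validated ridge selection on the
   default cohort lands at a comparable penalty (~0.17–0.21); 0.1 is fixed
   for determinism. `ridge = 0` restores a plain `glm`.
4. **Scaling.** `Score = A − B·ln(odds)` with `B = PD0/ln 2` and
   `A = P0 + B·ln(odds0)`. The shipped calibration — baseline odds 1/19,
   P0 = 70, PD0 = 4.14 points per doubling of the odds — gives A = 52.41,
   B = 5.97. Higher MAS odds mean lower scores.
5. **Points.** Each feature-bin contributes
   `round(base_share − B·coef·WOE)` points, with the intercept-derived base
   `A − B·intercept` spread equally across features (standard scorecard
   practice). Before rounding the total equals `A − B·ln(odds)` exactly;
   rounding changes it by at most half a point per feature. Totals are
   clamped to [0, 100] for presentation; the raw total is also returned.
6. **Threshold.** The Kolmogorov-Smirnov statistic over ascending scores:
   the decision threshold is the (lowest, on float-tolerant ties) score
   maximizing |CDF_MAS − CDF_SLE|, and `score ≤ threshold` predicts MAS.
7. **Risk bands.** Gaussian kernel densities (Silverman bandwidth,
   overridable) for the two classes' scores; the risk of a unit score
   interval is the prior-weighted share of the positive density's mass in
   that interval — with the balanced default prior this is exactly the
   probability that a patient scoring there is a MAS case. For each level
   95/75/25/5% the band boundary is the highest score (on a quarter-point
   grid) whose risk still reaches the level, giving five contiguous bands
   from extremely high to extremely low risk. Sub-integer boundaries keep
   the bands strictly ordered even when the risk falls steeply — a steep
   transition shows up as a narrow band, not a failure. Non-monotone risk
   or unattainable levels raise errors naming the offending scores rather
   than producing incoherent bands.

`score_patient()` bins raw values (out-of-range values fall into the
terminal bins), sums points, and returns the score, band, interval risk,
KS-rule prediction, per-feature point contributions, and a −1/0/1 flag per
feature against its reference interval so threatening values can be
highlighted.

## Numerical choices, in one place

| Choice | Value | Why |
|---|---|---|
| imputation tiers | 5% / 20% | below: mean/mode suffices; above 20%: refuse |
| RF imputer | 100 trees, ≤10 sweeps, tol 1e-3 | stability at n≈200 |
| fence multiplier k | 1.5 | Tukey convention |
| Pearson / VIF cutoffs | 0.8 / 10 | conventional screens |
| LASSO CV | 5 folds × 5 repeats, deviance, 1-SE rule | stability + overselection control (see above) |
| WOE smoothing | +0.5 on zero cells | finite WOE |
| ChiMerge | 20 quantile pre-bins, α = 0.05, 3–8 bins | skew-robust; small-cohort bin counts |
| WOE-LR ridge | 0.1 | score-scale representability |
| scaling | odds0 1/19, P0 70, PD0 4.14 | published calibration (A 52.41, B 5.97) |
| KDE bandwidth | Silverman (`nrd0`) | standard default, overridable |
| KS ties | lowest score, 1e-9 tolerance | determinism across float noise |
| probability threshold (classifiers) | 0.5 | scorecard has its own KS threshold |
| Z-score | population SD | exact two-point standardization |

## Problem sizes

The shipped defaults are desk-scale by design: cohorts of 188 (94 + 94)
with 33 candidate features, 50-seed Monte-Carlo loops for the selection
benchmark, 200-seed loops for the distribution-level calibration checks at
n ≤ 5 000, and leave-one-out validation on the 150-patient training split.
A full default `run_pipeline()` completes in well under a minute on one
core.

## Known limitations

* The scorecard's "validation" column is apparent (training-sample)
  performance; only the test and external columns are honest estimates of
  generalization.
* With a strongly separable training cohort the training KS statistic is
  1.0 and the risk transition is steep; band boundaries then sit close
  together. Real cohorts with more overlap produce wider bands.
* The KDE risk is a ratio of smoothed densities; far outside the observed
  score range it relies on Gaussian tails and should not be interpreted.
* The iterative forest imputer is single-imputation; no between-imputation
  variance is propagated.
* Feature screening before the train/test split means the split does not
  guard the screening stage itself.
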