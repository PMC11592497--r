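---
title: "Methods: explainable survival machine learning for post-surgery mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable survival machine learning for post-surgery mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(survxplain)
```

## The problem

In-hospital mortality after surgery for congenital heart disease (CHD) is a
rare, strongly structured outcome: most children are discharged alive within
days, a small fraction die in hospital, and both the risk and the follow-up
duration differ by an order of magnitude between disease groups
(univentricular palliation stages versus simple biventricular corrections).
`survxplain` implements a complete, reproducible analysis workflow for this
setting: survival machine-learning models are tuned, validated in repeated
cross-validation, evaluated on an independent holdout set with Harrell's
concordance index, and then *explained* — per-model Shapley attributions and
time-dependent SurvSHAP(t) curves are aggregated across all repeated-CV
models instead of trusting any single fit.

Because real paediatric heart-surgery registries cannot be shipped, the
package includes a first-class synthetic cohort generator that reproduces
the statistical structure the analysis assumes. Every stage of the pipeline
is therefore testable end to end.

## The synthetic cohort generator

The generator (`cohort_spec()`, `generate_cohort()`) draws one record per
patient in four disease groups — `UVHD I`, `UVHD II`, `BVHD cmplx.`,
`BVHD smpl.` with default sizes 50/111/291/850 (1302 patients) — and
emulates:

* **Discharge as censoring.** A latent death time $T$ and a latent
  discharge time $D$ compete; the observed follow-up is $\min(T, D)$ with
  status *deceased* iff $T \le D$. Discharge times are lognormal per group
  with medians 17/14/10/6 days and log-sds 1.10/0.99/0.66/0.35 chosen from
  the interquartile spans typical of each group.
* **Proportional-hazards death times.** $T$ follows a Weibull law with a
  shared shape $k = 1.2$ (mildly increasing hazard early after surgery) and
  a group-specific baseline scale; the hazard is multiplied by
  $\exp(\beta^\top x)$, implemented as scale division by
  $\exp(\beta^\top x / k)$. Continuous covariates are standardised
  cohort-wide before $\beta$ is applied, so effects are per standard
  deviation and comparable across covariates.
* **Planted effects.** The default effect vector is the recovery target of
  the whole workflow: creatinine maximum (+0.9 per sd, the strongest),
  open thorax (+0.6), circulatory arrest (+0.45), and UVHD I membership
  (+0.8). These make Table-style importance recovery a testable property.
* **Calibrated group mortality.** The four baseline Weibull scales
  (60.5, 300.9, 177.2, 615.4 days) were calibrated once by Monte Carlo —
  sampling the planted linear predictor from a large cohort and solving
  $P(T \le D) =$ target per group with the analytic Weibull CDF against
  simulated discharge draws — so that group mortality is close to
  62 / 7.2 / 9.6 / 0.7 per cent. They are frozen constants, not tuned
  per run; across 50 seeds the mean group mortality lands within about
  1.6 percentage points of each target.
* **72 h laboratory series.** Each analyte (creatinine, urea, CRP,
  leukocytes) gets 4–8 draws at uniform random hour offsets in [0, 72],
  lognormal around a group-shifted patient-level mean. The series length is
  deliberately variable: no sampling frequency is canonical for the first
  72 h after surgery, and the min/max feature engineering must cope with
  any series length, including a single draw.
* **MCAR missingness.** `inject_missingness()` perforates raw fields
  independently (defaults: weight 2.23 %, height 0.08 %).

What the generator does **not** emulate: real physiology (lab values are
noise around group means, not kidney-function trajectories), treatment
policy, informative (MNAR) missingness, or correlations between surgery
descriptors beyond group membership. Passing tests on synthetic data
therefore demonstrate that the *pipeline machinery* is correct and that
planted signal of realistic strength is recovered — they are not evidence
about any real cohort.

## Preprocessing and feature engineering

`impute_chained()` implements chained-equation imputation: numeric columns
by predictive-mean matching (Bayesian coefficient draw, five nearest
donors), two-level factors by a logistic draw, ten cycles, one completed
dataset. One completed matrix (rather than pooled multiple imputations) is
used because the downstream consumer is an ML matrix, not a pooled
inferential estimate. Imputation is fitted on the full cohort before
splitting — feature engineering follows imputation in the workflow order —
a documented, deliberate trade-off: with missingness this sparse it
changes little, and it guarantees one complete matrix for every
downstream stage.

`engineer_features()` applies the clinical recoding rules: weight below
2500 g becomes a binary marker and the raw weight column is dropped; height
and age at admission are dropped as near-collinear with age at surgery;
total duration of stay is dropped because it is a linear combination of the
waiting time and the outcome; the hospitalisation history collapses to the
most severe past group under the severity ranking UVHD Ia > UVHD Ib >
BVHD cmplx. > UVHD II/III > BVHD smpl.; and each 72 h lab series collapses
to its clinically adverse extreme (maxima for creatinine, urea, CRP;
minimum for leukocytes). The result is exactly 19 predictors plus the
survival outcome.

`censor_followup_outliers()` censors follow-up times above the 99.5 %
quantile, computed on the whole cohort with the standard
linear-interpolation quantile definition (R type 7), truncating those rows
to the threshold and forcing their status to censored.
`prune_correlated()` screens continuous predictor pairs at |r| ≥ 0.7; the
shipped predictor set produces an empty report on default synthetic data.

## Splitting

`stratified_partition()` and `repeated_cv_folds()` stratify on the crossing
of five quantile bins of follow-up time, event status, and disease group.
Five bins are a compromise: enough resolution to balance the skewed
follow-up distribution, coarse enough that cells still hold several
patients; duplicate quantile breaks merge sparse cells with the nearest
time bin automatically. Within each stratum, allocation is a random-offset
cyclic fill, with one cyclic counter per status level carried across
strata. This yields fold sizes differing by at most one within every
stratum *and* event counts per fold within one of proportionality — with
only 73 events in 1302 patients, event balance is the binding constraint.
Singleton strata go to train (split) deterministically for
reproducibility.

## Models and the risk contract

All three families sit behind one contract: `predict_risk()` returns one
finite number per observation, higher meaning higher mortality risk, which
is all that Harrell's C-index needs; `predict_survival()` is exposed where
the family supports it.

* **RSF** (`fit_rsf()`, backed by `ranger`): risk is the ensemble
  cumulative hazard summed over the event-time grid — the standard
  ensemble mortality measure. Survival functions come from the forest.
* **Boosted Cox** (`fit_boosted_cox()`, backed by `xgboost` with the Cox
  partial-likelihood objective): risk is the boosted linear predictor on
  the log-relative-hazard scale. Whether such scores are exponentiated
  before ranking is immaterial for concordance (the map is monotone), so
  the raw margin is used. Early stopping (default patience 500 rounds)
  requires an explicit validation fold; the realised round count is logged
  in the model metadata. `num_rounds = 0` is a valid configuration that
  predicts a constant — useful as a null model.
* **CPH** (`fit_cph()`, backed by `survival::coxph`): Breslow tie handling
  throughout, matching the boosted-Cox objective's convention; risk is the
  linear predictor relative to zero covariates, and the Breslow baseline
  cumulative hazard provides survival functions.

Hyperparameter configurations are validated against the search-space
bounds (RSF: trees 100–1000, depth 1–40, mtry 2–9, node size 1–20, sample
fraction 0.3–1; boosted Cox: depth 1–40, learning rate 0.001–0.2,
subsample and column subsample 0.3–1, min child weight 0–10).

## Tuning

`bayesian_optimize()` maximises the mean stratified 3-fold CV C-index.
The surrogate is a Gaussian process with a Matérn-5/2 kernel on the
unit-scaled search space (fixed length-scale 0.3, small nugget); the
acquisition is the upper confidence bound $\mu + \kappa \sigma$ with
$\kappa = 3.5$, favouring exploration. Initialisation samples settings
from the min/max/step grid pool; subsequent proposals maximise the UCB
over random candidates anywhere inside the bounds, so the grid seeds but
does not constrain the search. A failing objective evaluation is recorded
as failed and skipped by the surrogate. The full budget is 50
initialisation + 128 guided evaluations; the `reduced` profile ships
8 + 8, which is enough to separate reasonable from unreasonable settings
on desk-scale synthetic data.

## Evaluation

`harrell_c_index()` uses the classical definition: a pair is comparable
iff the earlier observed time is an event and the two times are not tied
(tied event times are excluded — conventions differ between
implementations, so this choice is documented and pinned by a brute-force
oracle test); tied risks earn half credit. `evaluate_ensemble()` applies every
repeated-CV model to the holdout set, overall and per disease group, and
reports mean ± sd per family; a group subset without comparable pairs is
reported as `NA` rather than raising.

## Attributions

`shap_attributions()` implements two estimators around one coalition
machinery, where the value of a coalition is the model's mean prediction
over a background dataset with coalition features taken from the explained
observation:

* **Exact enumeration** for p ≤ 10 (cost $2^p$), used by the test suite as
  the ground-truth oracle.
* **Antithetic permutation sampling** (default 64 permutations, each
  forward permutation paired with its reversal, per-observation seed
  schedule) for the full 19-feature setting.

Both satisfy additivity exactly by construction (telescoping sums):
base value + attributions = model prediction, which the suite asserts at
1e-9. The background set is the explained model's own training fold,
never the holdout, so base values cannot leak test information.
Attributions are computed on each family's own risk scale (cumulative
hazard for RSF, log relative hazard for boosted Cox); magnitudes are
therefore never compared across families, only ranks.

`aggregate_shap_over_models()` averages attributions element-wise across
the repeated-CV models (per observation and feature), and derives the
mean-|phi| ranking with lexicographic tie-breaks — ties are vanishingly
rare with continuous attributions, but a deterministic ranking makes the
emitted tables reproducible. `top_k_rank_frequency()` counts, per feature,
the CV models ranking it in the top five; `group_force_summary()` emits
per-group signed means, the data behind group-stratified force plots.

`survshap_curves()` generalises the same machinery to survival functions:
the coalition value is the mean predicted survival curve over the
background, producing one attribution curve per feature that sums, at
every grid time, to $S(t\,|\,x) - \bar S(t)$. The grid is the training
fold's unique event times, quantile-thinned to at most 200 points (30 in
the reduced profile) to bound curve sizes. SurvSHAP(t) runs only for
families exposing survival functions — RSF (and CPH), not boosted Cox.
`global_survshap()` and `aggregate_survshap_over_models()` average over
observations and models respectively.

## The end-to-end pipeline and the reduced profile

`run_end_to_end()` executes simulate → preprocess → split → tune →
validate → explain → CPH comparison → report, writing every tabular
artifact as CSV plus a JSON manifest (stage status, artifact paths, seeds,
configuration hash). Stage seeds derive deterministically from one master
seed; identical configuration and seed reproduce every artifact byte for
byte. The CPH comparison uses the union of each family's top-5 features by
aggregated mean |phi|, mirroring how a conventional regression would be
informed by the ML feature importance.

The `reduced` profile is the desk-scale configuration used by the test
suite and the acceptance script: 10×10 repeated CV is kept in full (100
models per family — the aggregation claims depend on it), but tuning uses
8 + 8 evaluations, SHAP explains 20 holdout observations with 6
permutations against 12 background rows per model, and SurvSHAP(t) runs on
3 RSF models with 12 observations. These sizes were chosen so a complete
run takes minutes on one CPU while keeping the Monte-Carlo error of
per-model mean-|phi| rankings well below the planted-signal margin; the
`full` profile restores the full-scale budgets.

## Numerical choices and degenerate inputs

* Quantiles everywhere use linear interpolation between order statistics
  (R type 7), so the outlier-censoring threshold is reproducible.
* Weibull hazard scaling uses the exact scale transform
  $\lambda \mapsto \lambda e^{-\beta^\top x / k}$, not an approximation.
* The GP surrogate adds a 1e-10 jitter and a small nugget before the
  Cholesky factorisation; candidate proposals falling on already-evaluated
  settings are resampled.
* Empty lab series, fully missing columns, collinear CPH designs, unknown
  disease-group labels, and out-of-bounds hyperparameters raise immediate,
  named errors rather than propagating silently.
* Lab series with a single draw give min = max = that draw; constant
  columns impute to the constant.

## Known limitations

* The synthetic cohort is a structural emulation, not a clinical
  simulator; absolute effect sizes and attribution magnitudes have no
  clinical meaning.
* Because the group mortality targets force baseline hazards an order of
  magnitude apart, the disease group acts as an implicit planted feature
  that is stronger than any single coefficient in `beta` on the
  *cumulative-hazard* scale. In per-model rankings the RSF (explained on
  that scale) therefore frequently places the disease group above the
  creatinine maximum, while the boosted-Cox family (explained on the
  log-hazard scale) recovers creatinine as the top feature almost always.
  The emitted rank-frequency tables make this scale dependence visible;
  it is a property of the attribution scale, not an estimator defect.
* Single-dataset chained imputation before splitting leaks marginal
  distribution information across the split boundary (documented above).
* The boosted-Cox family exposes no survival function, so SurvSHAP(t) is
  RSF-only in the default pipeline.
* Attribution sampling error is controlled by permutation count, not
  estimated adaptively; the exact estimator is available up to ten
  features for verification.
* No competing risks, time-varying covariates, or interaction (pairwise)
  attributions.
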