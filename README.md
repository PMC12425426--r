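# actidep

Depression detection and severity grading from wrist-worn actigraphy, as a
tested, reusable R pipeline.

Clinical actigraphy records gross motor activity once per minute for days at
a time. Depressed individuals tend to show lower and more rigid rest–activity
patterns: reduced mean activity, disrupted circadian timing, and higher
autocorrelation. `actidep` turns raw per-minute count recordings into a
day-level feature matrix, trains and compares a roster of classifiers for two
tasks — *depressed vs control* and three-level *severity* (MADRS 0–6 normal,
7–19 mild, 20–34 moderate) — and explains the fitted models with Shapley
values and LIME surrogates. A synthetic circadian cohort generator with
planted group effects makes the entire pipeline testable without access to
clinical data.

The package is aimed at researchers in digital phenotyping and computational
psychiatry who want a transparent, fully seeded reference implementation of
this analysis rather than a black-box script.

## What it computes

**Features (per participant-day window of 1440 minutes).** Time domain: mean,
SD, skewness, kurtosis, IQR, lag-1 autocorrelation, normalized histogram
entropy. Frequency domain (Welch averaged periodogram, 256-min Hann segments,
50% overlap): PSD mean, dominant frequency, spectral entropy. Circadian:
activity onset and offset from a smoothed threshold crossing. Transition:
entropy rate of the tertile-discretized activity-state Markov chain,

H = −Σᵢ πᵢ Σⱼ Pᵢⱼ log Pᵢⱼ / log k ∈ [0, 1].

Demographics (age-band midpoint, gender) complete the 15-column matrix,
standardized by z = (x − μ)/σ with training-fold statistics.

**Class balancing.** A from-scratch ADASYN implementation: each minority
point i receives a synthesis budget proportional to rᵢ = (majority neighbors
among its K nearest)/K, and synthetic points are convex combinations
s = xᵢ + λ(x_z − xᵢ) with a same-class neighbor x_z, λ ~ U(0,1).

**Evaluation.** Five classifiers (logistic regression, RBF SVM, random
forest, gradient-boosted trees, feed-forward neural network) under 3×10
repeated stratified cross-validation, participant-grouped to prevent identity
leakage, scored per fold by F1. Metrics from the confusion matrix include
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Model differences are
tested with paired two-tailed t tests against the boosted reference and Holm
step-down correction at α = .05.

**Explanation.** Exact coalitional Shapley values
φᵢ = Σ_{S⊆N∖{i}} |S|!(|N|−|S|−1)!/|N|! · [v(S∪{i}) − v(S)] by full subset
enumeration (≤ 16 features), an unbiased permutation-sampling estimator for
larger p, global mean-|φ| importance rankings, cross-model rank agreement,
and LIME threshold-rule surrogates fitted by kernel-weighted ridge regression
over quartile-bin indicators.

## Worked example

```r
library(actidep)

cfg <- run_config(
  task      = "binary",
  synthetic = synthetic_cohort_config(seed = 42),  # 23 condition / 32 control
  models    = c("logistic", "gradient_boosting"),
  seed      = 42)
res <- run_pipeline(cfg)
print(res$cv)
#> <cv_result> binary task, 3 x 10 folds
#>   logistic           F1 = 0.844 +/- 0.123
#>   gradient_boosting  F1 = 0.897 +/- 0.084
print(res$significance[, c("comparison", "p_raw", "p_adjusted", "reject")])
#>                      comparison      p_raw p_adjusted reject
#> 1 gradient_boosting vs logistic 0.01243543 0.01243543   TRUE
head(res$explanations$gradient_boosting$ranking, 3)
#>    feature mean_abs_phi rank
#> 1 skewness   0.21699173    1
#> 2 kurtosis   0.09130577    2
#> 3      iqr   0.06913928    3
```

The per-fold F1 means say the boosted trees separate the groups better than
the linear baseline on this cohort; the Holm-adjusted paired t test confirms
the gap is systematic rather than fold noise. The importance ranking is the
mean absolute Shapley attribution per feature: here distribution-shape
features carry the decision, consistent with the planted group structure
(the subtype mixture changes the shape of the daily count distribution more
than its location). (Exact numbers vary with the seed; rerunning with the same
seed reproduces them bit for bit.)

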