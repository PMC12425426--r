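---
title: "Actigraphy features and interpretable depression classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actigraphy features and interpretable depression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`actidep` implements an end-to-end analysis of clinical actigraphy for
depression: per-minute activity counts and a clinical scores table are merged
into a labeled cohort, segmented into participant-day windows, summarized
into a compact feature vector, and fed to a roster of classifiers for two
tasks — depressed vs control, and three-level severity from the
Montgomery–Åsberg Depression Rating Scale (MADRS: 0–6 normal, 7–19 mild,
20–34 moderate; the modeled cohorts contain no severe cases, and scores of
35+ are rejected unless explicitly mapped to a fourth class). Model
comparison runs under a repeated stratified cross-validation protocol with a
paired-t/Holm significance layer, and the fitted models are interrogated
with Shapley attributions and LIME surrogates.

This vignette is the package's methods account: the model and estimator
choices, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical conventions
for degenerate inputs.

# Analysis unit and leakage control

The analysis unit is one **participant-day**: a window of L = 1440
one-minute epochs. Day windows match the recording cadence and give enough
rows for cross-validation on cohorts of a few dozen participants. Two
consequences follow:

* every window inherits its participant's label, so rows are not
  independent;
* all windows of a participant are therefore kept in the same CV fold
  (stratification and fold assignment operate on participants, not rows).
  Without this, adjacent days of the same person appear on both sides of
  the split and inflate every score.

Timestamp gaps up to 2 minutes are zero-filled; a window spanning a longer
gap is dropped and logged. Trailing partial windows are dropped.

Severity labels use `madrs1` (the score at inspection start) by default;
`madrs2` or their mean are config options. Controls without a recorded
score are class 0. Age enters the feature set as the midpoint of the
age-band string ("45-49" → 47); gender keeps the dataset's 1/2 coding.

# The feature set

Thirteen activity features plus age and gender. Conventions for degenerate
inputs are explicit because flat or all-zero days do occur (device off,
hospital admission): a constant window has sd = 0 and, by convention,
skewness = kurtosis = autocorrelation = entropy = 0; windows whose features
are undefined (no circadian crossing, zero spectrum) are dropped and logged
rather than imputed.

**Time domain.** Mean, sample SD, adjusted Fisher–Pearson skewness, excess
kurtosis, IQR with linear-interpolation quantiles, lag-1 sample
autocorrelation (the lag is configurable), and the Shannon entropy of a
16-bin equal-width histogram normalized by log 16 so it lies in [0, 1].
Histogram and quantile definitions make the entropy features invariant to
rescaling all counts, while mean and SD scale linearly — a tested property.

**Frequency domain.** The power spectral density is estimated by Welch's
averaged modified periodogram: 256-minute Hann-tapered, mean-removed
segments at 50% overlap, one-sided scaling calibrated so that the PSD sums
to the sample variance (a Parseval check in the tests guards the
convention). Reported: mean PSD ordinate excluding DC; dominant frequency
(argmax over DC-excluded bins, in cycles/minute); spectral entropy, the
normalized Shannon entropy of the DC-excluded PSD — near 0 for a pure tone,
near 1 for white noise. The segment length trades frequency resolution
(1/256 cycles/min) against averaging; with day windows it yields 10
overlapping segments.

**Circadian timing.** Counts are smoothed with a 60-minute centered rolling
mean (circular across midnight), compared against 1.0 × the daily mean, and
runs of at least 30 consecutive above-threshold minutes count as active.
Onset is the first minute of the first such run, offset the last minute of
the last. For a raised-cosine day profile this crossing sits a known offset
after the template's rising edge — span·acos(1 − f)/(2π) minutes, with f
the active fraction — which is what the recovery tests assert against. The
threshold multiple, persistence and smoothing width are configurable; the
defaults favor robustness to fragmented activity over sharp edge detection.

**Transitions.** Counts are discretized into k = 3 states by per-window
quantile (empirical CDF) binning — rank-based so that heavily tied values
such as long runs of zeros occupy one state — and the entropy rate
H = −Σᵢ πᵢ Σⱼ Pᵢⱼ log Pᵢⱼ, normalized by log k, is reported: 0 for
deterministic dynamics, 1 for uniformly random switching.

**Standardization.** z = (x − μ)/σ with per-feature population moments
fitted on training rows only and frozen; σ = 0 columns map to zeros with a
warning. Within each CV fold the scaler is fitted on the training partition
before oversampling, and applied unchanged to the held-out partition.

# Class balancing

ADASYN is implemented from scratch. For each minority class against the
pooled rest: the total budget is G = (m_majority − m_minority)·β (β = 1
equalizes counts); each minority point's difficulty is rᵢ = (other-class
neighbors among its K = 5 nearest in the full data)/K; budgets are allocated
proportionally to the normalized rᵢ with largest-remainder rounding (so
budgets sum exactly to G and ties differ by at most one). Synthesis draws a
partner x_z uniformly among the point's K nearest same-class neighbors and
returns xᵢ + λ(x_z − xᵢ), λ ~ U(0, 1). If no minority point has other-class
neighbors the allocation falls back to uniform with a warning; a minority
class of size one is an error. Oversampling runs inside each training fold,
after scaler fitting — the leakage-safe ordering; oversampling before the
split would contaminate held-out rows with synthetic copies of themselves
and is deliberately not offered as a default.

# Models and the comparison protocol

Five classifiers behind one interface: logistic regression (glm binomially
for two classes; multinomial or one-vs-rest for three), an RBF support
vector machine (cost 1), a 300-tree random forest, gradient-boosted trees,
and a feed-forward neural network. Boosting defaults are sized for cohorts
of a few hundred windows: 150 depth-2 trees, learning rate 0.1, 80%
row/column subsampling, minimum child weight 5 — deliberately shallow and
regularized, since deeper settings overfit participant-clustered data of
this size. The neural network is a single hidden layer of 16 units with
weight decay 10⁻³ and a 500-iteration cap: the installed feed-forward
engine supports one hidden layer, and at these sample sizes a second layer
adds variance without accuracy. All hyperparameters are overridable per
model through the run config.

The protocol is 10-fold stratified cross-validation repeated 3 times (30
folds), identical fold sequence for every model, per-fold F1 (class 1
positive for the binary task; support-weighted for severity — with that
averaging, multiclass recall equals accuracy, an identity the tests assert).
Remaining metrics are computed from fold-pooled confusion matrices.
Multiclass MCC is the generalized correlation on the full k×k matrix, not a
per-class average. Paired two-tailed t tests compare the boosted reference
with each rival on the 30 paired scores; Holm's step-down controls the
family-wise error rate at α = .05. Degenerate difference vectors have
explicit conventions: all-zero differences give p = 1, identical nonzero
differences give p = 0 with a flag, both with warnings.

# Explanations

**Shapley.** The value function follows the marginal-replacement form:
v(S) is the mean model score over a background sample with the features in
S taken from the explained instance. The background defaults to a seeded
subsample of 50 training rows; a single baseline vector is a config option.
Exact enumeration computes every v(S) once (2^p coalition values, batched
through the model) and is refused above p = 16 features, where the
permutation-sampling estimator takes over: unbiased marginal contributions
along sampled feature orderings, with the residual of the efficiency
identity Σφ = f(x) − v(∅) redistributed equally at the end (and flagged).
Efficiency, symmetry and dummy axioms are asserted exactly in the tests;
the sampled estimator is tested against the exact oracle. Multiclass models
are explained per class score. Tree-specific fast Shapley is intentionally
out of scope — enumeration plus sampling stays model-agnostic and testable
against the definition.

**LIME.** Features are discretized into quartile bins of the training data.
Perturbations redraw each feature's bin uniformly (keeping the instance's
value when its own bin is drawn, otherwise sampling uniformly inside the
drawn bin); the interpretable representation is the binary same-bin vector.
Samples are weighted by exp(−d²/w²) on the binary distance with
w = 0.75·√p, and a ridge-regularized weighted least squares fit gives one
signed weight per feature, reported as threshold rules such as
`0.74 < autocorr <= 0.78`. Defaults: 5000 samples, top 10 rules, penalty
0.01. Fit quality is reported as the kernel-weighted R². Note what that R²
can and cannot reach: the binary surrogate can represent models that are
(locally) linear in the bin indicators almost perfectly, but for models
linear in the raw features most variance lies within bins and R² is
structurally small — it is reported, never used to discard an explanation.
Degenerate-spread features get no rule, with a warning.

**Global importance and cross-model comparison.** Mean |φ| per feature over
a set of explained instances, sorted. Two models' rankings are compared by
Spearman rank correlation, top-k overlap and per-feature rank deltas —
always within each model's own attribution scale, never across raw
magnitudes, because probability-scale attributions are not commensurable
across model families.

# The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. It
emulates the statistical skeleton of a clinical actigraphy cohort, not any
real dataset's distributions.

Per participant, counts are
max(0, round(b + A·template(t − φ) + ε_t)) where the template is a
raised-cosine day profile that is zero outside an active span, b is a basal
(tonic) activity level, and ε_t is stationary Gaussian AR(1) noise
(marginal sd 50 counts). MADRS scores are drawn from group-specific
truncated normals — controls N(2, 2) in [0, 6], conditions N(18, 6) in
[7, 34] — so generated labels always map consistently through the severity
cutoffs. Moderate cases (MADRS ≥ 20) receive a further 0.85× amplitude and
+30-minute phase increment, giving the three-class task learnable
sub-structure.

Default group structure (23 condition / 32 control participants, 7 days
each, matching the canonical clinical cohort's imbalance):

* controls: amplitude 300 ± 35, onset 420 ± 35 min, span 960 ± 50 min,
  AR(1) 0.4 ± 0.1;
* condition, psychomotor-retarded subtype (65%): amplitude 260, onset
  delayed to 510, span shortened to 760 — less activity, later and shorter
  active periods;
* condition, agitated subtype (35%): control-level amplitude, onset
  advanced to 300, span extended to 1080 — restless, phase-advanced
  activity;
* condition noise autocorrelation raised to 0.5.

The two-subtype design is deliberate and matters for what the package can
demonstrate. Depressed cohorts are clinically heterogeneous — psychomotor
retardation and agitation both occur — and the mixture makes the group
boundary non-monotone in several features: the retarded subtype sits below
controls in mean activity while the agitated subtype deviates on the
opposite side in timing. A linear model can exploit the net mean-activity
shift (standardized effect d ≈ 1 at 50 participants/group, a recoverability
property the tests check by simulation) but not the subtype structure;
tree ensembles can, which is why the boosted model outperforms the logistic
baseline on replicate default cohorts — a planted, recoverable analogue of
the ordering the analysis is designed to detect. The basal-activity
parameter exists because a basal contrast moves *only* the mean feature
(dispersion, shape, entropy and DC-excluded spectral features are all
shift-invariant), giving importance-recovery tests a planted effect with an
unambiguous proxy.

What the generator does **not** emulate: count-distribution detail (counts
are truncated rounded Gaussians, not a fitted count model), weekday/weekend
structure, missing-data patterns, device artifacts, medication or
comorbidity covariates, and any real cohort's exact feature distributions.
Passing the recovery tests therefore shows the pipeline detects the kinds
of structure it is built for at realistic effect sizes; it does not certify
performance numbers on clinical data.

# Problem sizes and numerical choices

Simulation-backed tests use deliberately scaled problem sizes: replicate
cohorts for the end-to-end recovery checks run at 50 participants/group
with 5-day recordings (CV/significance, 20 replicates) and 3-day recordings
(importance recovery, 10 replicates); the feature Monte-Carlo checks use
200 draws; the transition-entropy law-of-large-numbers check uses sequences
of 10⁵. These sizes keep the full suite fast while leaving each check's
statistical margin comfortable.

All randomness flows from explicit integer seeds; child seeds for stages
(generation, fold assignment, per-fold ADASYN, training, background
subsampling, permutations, LIME) are derived arithmetically from the global
seed, so a single integer reproduces a pipeline run bit for bit. Ties in
quantile binning follow average ranks; zero denominators in metrics return
0 with a warning; σ = 0 features standardize to zero with a warning.

# Known limitations

* Exact Shapley is exponential in p; beyond 16 features only the sampled
  estimator is available, and its per-feature Monte-Carlo error must be
  managed through the permutation count.
* The onset/offset estimator assumes a unimodal main activity period;
  strongly biphasic days yield the first and last sustained crossing, which
  may bracket a midday trough.
* Severity analysis needs each class represented by at least k participants
  for k-fold stratification; small cohorts need a reduced k or a larger
  simulated cohort.
* The LIME surrogate's R² is informative only relative to the binary bin
  representation (see above).
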