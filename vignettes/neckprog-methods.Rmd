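---
title: "Methods: synthetic cervical cohorts, feature extraction, and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cervical cohorts, feature extraction, and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the modelling assumptions, parameters, and numerical
choices behind `neckprog`. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. Study design being emulated

The generator's defaults emulate a three-group observational study of neck
pain: 15 healthy controls, 22 participants with recurrent neck pain (RNP)
after a whiplash injury, and 8 participants with chronic neck pain (CNP).
All participants are assessed once at baseline; the RNP group is then
followed monthly for 12 months, with the 6-month neck-disability score and
the monthly number of days with pain as prognostic outcomes.

Baseline assessment covers:

- **Cervical kinematics** (inertial sensor, 100 Hz): repeated maximal
  flexion–extension and rotation movements; per-movement range of motion
  (RoM), mean and peak angular velocity, and smoothness as the number of
  velocity peaks (NVP) — the count of angular-acceleration zero crossings.
- **Joint position error (JPE)**: eyes-closed head repositioning after
  rotation; the error is the angular distance between the start and return
  positions, averaged over three trials per side.
- **Craniocervical flexion (CCF) activation** (surface EMG of the
  sternocleidomastoid and scalene muscles, 2000 Hz): activation at
  progressive low-load stages, expressed as a percentage of each muscle's
  own maximal-contraction amplitude. Values above 100% are possible and are
  preserved: a submaximal coordination task can recruit a superficial muscle
  harder than that muscle's brief maximal test did.
- **Maximal strength**: craniocervical flexion force and multi-cervical-unit
  flexion/extension strength, taken as the best smoothed peak across trials.
- **Questionnaires**: neck disability, kinesiophobia, health-related quality
  of life, pain history (episode count, episode intensity).

## 2. The generative model

### 2.1 Baseline features

Each group has a mean and common standard deviation per feature
(`default_feature_params()`), sampled as independent truncated normals
within plausibility bounds (non-negative amplitudes, bounded questionnaire
scales). Group eligibility is enforced: RNP participants have at least two
prior pain episodes (truncated negative binomial), CNP participants have a
disability score of at least 10/50 and current pain of at least 20/100.

Independence across features within a participant is a deliberate
simplification: it leaves group *contrasts* faithful while making
identifiability of the outcome model exact and analysable.

### 2.2 Outcomes

Outcomes follow a known linear truth (`synthetic_truth()`):

- 6-month disability: `ndi6 = 10.23 + 0.54 * episodes − 0.32 * mvc_flexion`
  plus Gaussian noise (SD 3.5), truncated to the 0–50 scale.
- Days with pain per month: mean `2.14 + 0.40 * episodes`, decomposed into a
  between-participant random effect (SD 2.6) and month-level noise (SD 2.7),
  so that the participant's 12-month mean — the quantity the prognostic
  model predicts — retains realistic residual dispersion instead of
  averaging away. A month only contributes its days when its mean pain
  intensity reaches 20/100. Day counts are kept continuous so the noiseless
  generator is exactly linear and parameter recovery can be verified to
  machine precision.
- Dropout is monotone: once a participant misses a month, all later months
  are missing. Prognostic models use complete cases only.

With the noise switched off, the package's own two-step workflow recovers
the generating coefficients exactly; with noise on, recovery is checked
against the exact OLS sampling distribution rather than an arbitrary
closeness threshold (see `tests/testthat/test-synthetic.R`).

### 2.3 Raw recordings

When `recordings = TRUE`, each participant also gets raw signals consistent
with their drawn features:

- **Cyclic movements**: a raised-cosine carrier
  `theta(t) = −(A/2) cos(2 pi t / P)`. Each half-cycle then has exactly one
  velocity peak, so the noiseless NVP is exactly 1 and any excess is
  attributable to the added ripple. The per-movement amplitude is half the
  combined flexion+extension feature, and the period is set from the target
  mean velocity, so extraction round-trips the drawn RoM and velocity.
- **Smoothness**: an 8 Hz ripple — inside the 10 Hz analysis pass band —
  whose amplitude is modulated by the participant's target NVP.
- **JPE trials**: rest, raised-cosine ramp to the target, hold, ramp back to
  an offset equal to the drawn error, rest.
- **EMG**: band-limited noise whose whole-trace RMS is scaled to the target
  fraction of the maximal trial; submaximal trials reuse the maximal trial's
  noise realisation so that normalised activation equals the target
  fraction exactly, giving exact oracles for the normalisation chain.
- **Force**: a trapezoidal effort profile with optional noise.

### 2.4 What the generator does and does not emulate

Emulated: group contrasts in all tabulated features, the linear
outcome-generating process, follow-up dropout, and raw signals whose
*extracted* features match the drawn ones (round-trip tests bound the
discrepancy).

Not emulated: within-participant correlation between features;
non-stationary or asymmetric movement cycles; electrode artefacts, crosstalk
and fatigue in EMG; and — importantly — the absolute magnitude of realistic
NVP values. Real jerky movements carry acceleration content above the 10 Hz
analysis cut-off; a generator whose ripple lay above 10 Hz would have its
smoothness erased by the very filter the analysis prescribes. The 8 Hz
ripple therefore reproduces the *ordering* of smoothness across groups, not
absolute counts. For this reason the pipeline's group comparisons default to
the drawn feature table (`feature_source = "cohort"`), with extraction
fidelity verified separately.

## 3. Signal-processing choices

- **Filters**: 10th-order 10 Hz Butterworth low-pass for angles; 4th-order
  20–400 Hz band-pass for EMG; both zero-phase via forward–backward
  application (`signal::filtfilt`). Magnitude responses are verified in the
  tests against the closed-form bilinear-transform Butterworth response, and
  the two-pass gain is the square of the one-pass gain.
- **Edge handling**: `signal::filtfilt` zero-pads internally, which rings at
  the record edges. Signals are therefore extended by even (mirror-image)
  reflection — exact for recordings at rest at both ends — with pads of
  1.5 s (low-pass) and 0.5 s (band-pass), after which boundary transients
  are negligible.
- **Derivatives**: central differences on the uniform grid, one-sided at the
  two endpoints. The analytic-oracle tests compare interior movements, since
  a movement abutting the record boundary sees the one-sided stencil.
- **Segmentation**: velocity sign runs split the recording into directional
  movements; each movement is trimmed to where angular speed exceeds 5% of
  that movement's own peak — a per-movement reference that is robust to slow
  repetitions. An exhaustive scan oracle reproduces the boundaries in tests.
- **NVP counting**: acceleration sign changes outside a hysteresis band of
  1% of the movement's peak acceleration magnitude, suppressing chatter
  around zero.
- **Sliding RMS**: the maximal 1-s window RMS is computed from cumulative
  sums in O(n) and checked against a brute-force window scan.

## 4. Statistical choices

### 4.1 Group comparisons

Each feature is routed by an assumption-gated tree:

1. Shapiro–Wilk per group; if any p ≤ 0.05 the feature is analysed with
   Kruskal–Wallis and Bonferroni-adjusted Dunn post hocs (tie-corrected).
2. Otherwise Levene's test (centred on the mean); homogeneous variances go
   to one-way ANOVA with Tukey's HSD, heterogeneous to Welch's ANOVA with
   Games–Howell post hocs.

Post hocs run only after a significant omnibus test. Dunn and Games–Howell
are implemented in the package (no dependency provides them); Tukey, Welch
and Levene come from `stats` and `car`. The tests verify tie-corrected H by
hand, the ANOVA F on a hand-computed table, and the convergence of
Games–Howell to Tukey under equal variances; the tree's type-I error under
the null is measured by simulation in the acceptance tests.

### 4.2 Prognosis

A two-step workflow on the RNP group, complete cases only:

1. **Selection**: LASSO over the 15 baseline candidates
   (`table_predictors`), 5-fold cross-validation with a seeded fold
   assignment, penalty at the cross-validated minimum. Predictors are
   standardised internally; coefficients are reported on the original
   scale. The cross-validation minimiser is restricted to penalties whose
   active set leaves at least one residual degree of freedom for step two
   (`dfmax = n − 2`); this guard never binds at the default study sizes.
2. **Inference**: OLS on the selected predictors with per-term standard
   errors, t statistics, p-values and 95% confidence intervals from the t
   distribution with `n − k − 1` degrees of freedom, plus R², adjusted R²
   `1 − (1 − R²)(n − 1)/(n − k − 1)`, the F statistic
   `(R²/k) / ((1 − R²)/(n − k − 1))`, and in-sample RMSE on the outcome
   scale.

Selection and inference reuse the same data, so the reported intervals and
p-values are conditional on selection and optimistic in the usual way; the
scatter report (`scatter_fit_report()`) shows in-sample predictions against
the identity line for exactly this reason.

## 5. Design decisions on open points

- **Feature source for comparisons**: drawn table values by default (see
  §2.4); `feature_source = "extracted"` switches to features recomputed from
  the raw recordings.
- **Days-with-pain outcome**: modelled as the mean over observed months of
  the qualifying-day count (months below the 20/100 intensity threshold
  contribute zero), keeping the outcome on the days scale.
- **Degenerate inputs**: constant features are skipped in comparisons with a
  note; an all-zero penalty path (nothing selected) yields an explicit
  intercept-only model object rather than an error; movements too short to
  differentiate raise errors naming the problem.
- **Reproducibility**: every stochastic entry point takes a seed; the
  pipeline derives per-stage seeds from the run seed, writes them to the
  manifest alongside a configuration hash, and identical configurations
  reproduce byte-identical text outputs.

## 6. Limitations

- Synthetic features are independent within participant; multivariate
  structure (for example, correlated RoM and velocity deficits) is absent,
  so multivariable selection behaviour on real data may differ.
- NVP magnitudes are ordinal, not absolute (§2.4).
- Small groups (the CNP default is n = 8) make the normality gate
  low-powered; the tree then routes more features to parametric branches
  than ideal. This mirrors the analysis it emulates rather than improving
  on it.
- In-sample validation only: no external cohort, no optimism correction of
  R² or RMSE.
- The EMG generator produces stationary band-limited noise; spectral
  features (median frequency shifts, fatigue) are out of scope.
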