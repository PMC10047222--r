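---
title: "Methods: discriminating benign from atypical lipomatous tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating benign from atypical lipomatous tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altscore)
```

## The problem and the model

Atypical lipomatous tumors (ALT) are intermediate-grade fatty neoplasms
that recur locally, while benign lipomas do not; on MRI both can be almost
pure fat. The pipeline in this package takes a per-patient table of
MRI-derived features — binary findings (contrast enhancement, a
"STIR discrepancy", i.e. intralesional fluid signal without surrounding
fluid), categorical patterns, and continuous measurements (diameters,
septation thickness, fat fraction, ADC) — and produces three things: a
per-predictor diagnostic panel, a cross-validated predictor ranking, and an
unweighted additive score that calls ALT when at least 3 of 5 items are
positive.

The statistical chain is deliberately simple and fully reconstructible:

1. **Per-feature two-group tests.** Continuous features pass a Lilliefors
   Kolmogorov–Smirnov normality gate per group at α = 0.05; if both groups
   pass, an unpaired t-test is used; if not, but all values are positive
   and the log-transformed groups pass, the t-test runs on logs; otherwise
   Mann–Whitney U. Categorical features go to Fisher's exact test. These
   p-values are descriptive only — nothing downstream filters on them.
2. **Dichotomization.** Each continuous predictor is converted to binary at
   the Youden-optimal ROC cut-off (J* = max(Se + Sp − 1)), computed on the
   full sample. Candidate thresholds are midpoints between adjacent
   distinct values, which is why published cut-offs look like 125.5 mm or
   1.3 mm.
3. **Gain-ratio ranking.** For a discrete feature,
   GR = (H(class) − H(class | feature)) / H(feature), with entropies in
   bits. GR lies in [0, 1], is 0 at zero information gain and 1 exactly
   when the feature is a relabeling of the class. The ranking is
   cross-validated: the cohort is shuffled into 30 folds, GR is computed on
   each training split, and features are reported as merit mean ± SD and
   within-fold rank mean ± SD.
4. **Naive Bayes.** The "Bayes network" is fixed to the naive structure
   (class parenting every feature): with no published structure-learning
   settings, the naive factorization is the only reconstructible choice,
   and with 6 ALT among 45 patients anything richer would overfit. Priors
   and conditional tables are smoothed with a pseudo-count α per cell.
5. **Score.** The five best-ranked predictors become items; each item
   scores one point; ALT is called at ≥ 3 of 5. The score is evaluated at
   every possible cut-off 0..5 with the same 2×2 machinery as step 1,
   always in the ALT-positive orientation (sensitivity = fraction of ALT
   called), because a missed ALT is the costly error.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `k_folds` | 30 | The reference analysis used 30-fold CV; over 45 patients this gives folds of 1–2 cases. Folds are a seeded unstratified shuffle — stratifying 6 ALT across 30 folds is impossible. |
| `alpha` (NB smoothing) | 0.5 | A conventional half pseudo-count per cell; keeps every probability positive in folds that lose a class. `alpha = 0` (maximum likelihood, zero cells allowed) is supported. |
| `alpha_normal` | 0.05 | Normality-gate level of the test-selection procedure. |
| `top_k` | 5 | Number of score items. |
| `decision_cutoff` | 3 | Score threshold calling ALT (score range 0–5). |
| `ci_method` | `"wilson"` | Published intervals match neither Wilson nor Clopper–Pearson exactly, so the method is configurable and interval bounds are never treated as reproduction targets. |
| `var_equal` | `FALSE` | Welch t by default given the 39-vs-6 imbalance; the pooled Student t is one flag away since the source analysis only says "unpaired t-test". |

Fisher's exact test is two-sided by the sum-of-small-p rule (the sum of all
hypergeometric point probabilities not exceeding that of the observed
table, with a 1e-7 relative slack for floating-point ties). This matches
the published p = 0.0010 for the contrast-enhancement table; a mid-p
variant is deliberately not offered.

## The synthetic cohort generator

Patient-level data are not publicly available, so `default_cohort_spec()`
encodes the published per-group summaries (39 benign / 6 ALT) and
`simulate_cohort()` draws cohorts from them:

* **Marginals.** Binary features are Bernoulli at the published
  prevalences. Right-skewed positive quantities (septation thickness,
  volume, ADC) are moment-matched lognormals — printed SDs close to or
  above the means (volume 648.7 ± 757.8 mL) rule out untruncated normals.
  Roughly symmetric bounded quantities (age, diameters, sphericity,
  circularity, fat fraction) are truncated normals whose parent parameters
  are adjusted so the *post-truncation* mean equals the published mean
  exactly; the SD is matched by least squares. One published cell is
  unattainable within this family: a fat fraction of 73.3 ± 30.3 on
  [0, 100] exceeds the largest SD any truncated normal supports at that
  mean (the σ → ∞ limit is uniform, SD ≈ 28.9), so its simulated SD is the
  family maximum (≈ 23) while the mean is exact. Moment computations fall
  back to a log-weighted quadrature when the support sits deep in one tail
  of the parent, where the closed form loses all precision.
* **Joint structure.** Only marginals were published, so the joint
  distribution is a Gaussian copula whose correlation defaults to the
  identity and is a configuration knob, never inferred. Each feature draws
  its latent normals from a deterministic sub-stream derived from the
  global seed, the group and the feature name, so appending a feature
  never reshuffles existing columns; correlation is induced by the
  Cholesky factor afterwards, which leaves the back-transformed marginals
  untouched.
* **What it does not emulate.** Real cohorts have correlated features
  (large tumors enhance more often), measurement error, and missing
  values; the default generator has none of these. Consequently the
  pipeline separates synthetic groups more cleanly than real ones — a
  synthetic 45-patient cohort routinely yields CV classification rates in
  the high 90s against the 91.1% reported on real data. Passing tests on
  synthetic cohorts demonstrates correctness of the machinery and
  recoverability of effects of the published size, not clinical
  performance.

## Numerical and design choices

* **ROC.** The trapezoid AUC is computed over all midpoint thresholds plus
  ±∞ sentinels and is checked (to 1e-12, property-tested) against the
  tie-corrected rank statistic U/(n₁n₂). The reported direction is chosen
  so AUC ≥ 0.5; Youden ties break toward higher ALT sensitivity, then
  toward the smaller absolute threshold. Degenerate predictors (all values
  equal, J* = 0) are flagged and excluded from ranking rather than given
  an arbitrary cut-off. Cut-offs are selected on the full sample (matching
  the fixed published cut-offs); the fold-internal alternative would give
  variable cut-offs per fold and is out of scope.
* **Cross-validation.** One fold engine (`make_folds()`) serves both the
  ranking and the classifier: seeded shuffle, fold sizes differing by at
  most one, no stratification. A feature constant on some training split
  has undefined gain ratio there and counts as merit 0 for that fold; a
  training split missing a class is refitted through smoothing alone with
  a logged message.
* **Sentinels, not exceptions.** Zero denominators in diagnostic metrics
  yield `NA`; specificity = 1 yields LR+ = `Inf`; constant features yield
  `NA` gain ratio; groups with fewer than 2 usable values yield an `NA`
  comparison. Missing feature values are dropped listwise per feature
  (comparisons), marginalized by omission (naive Bayes), or scored 0 with
  a flag (score items) — never imputed.
* **Normality test.** "Kolmogorov–Smirnov" is interpreted as the
  Lilliefors variant (parameters estimated from the sample), via
  `nortest::lillie.test()`; the classical fixed-parameter KS is available
  behind a flag since the source description does not say which was used.
* **Orientation.** The published per-predictor table uses a benign-positive
  orientation in which "test-positive" is the *absence* of the worrying
  finding (only that convention reproduces its printed PPV 37/38 = 97.4%
  and NPV 5/7 = 71.4%); score evaluation uses the ALT-positive orientation
  (its published sensitivity of 100% is for detecting ALT). The
  `contingency_2x2()` constructor therefore carries the orientation as
  explicit metadata instead of hard-coding either convention.
* **Score range.** The score is the 0–5 integer count of positive items
  (six possible values); the decision cut-off ≥ 3 is a parameter, not a
  constant.

## Problem sizes used by the test suite

The suite exercises the documented properties at sizes chosen to keep a
full run around a minute: generator fidelity and copula checks at 50,000
patients per group (prevalences within ±0.01, means within ±2%,
within-group cross-feature correlations within ±0.02); Fisher equivalence
against full hypergeometric enumeration for every 2×2 table with total
≤ 30; AUC trapezoid/rank identity over 1,000 random instances; type-I
calibration of the dispatched two-group test over 2,000 simulated 39-vs-6
cohorts (rejection 0.05 ± 0.015); and end-to-end recovery, over 100 seeded
cohorts of 250 + 250 patients with exactly five informative features among
noise, of all five in the top ranks with a Youden-chosen score cut-off
reaching sensitivity and specificity ≥ 0.90.

## Known limitations

* The generator reproduces published *marginals*; any conclusion that
  depends on the real joint dependence structure (e.g. the exact CV
  classification rate) can only be bracketed, not reproduced.
* Published confidence intervals and a handful of internally inconsistent
  table cells (a sensitivity of 90.0 alongside counts implying a different
  denominator) cannot be regenerated from the printed counts and are
  excluded from fixed expectations.
* The gain-ratio merits of *continuous* predictors (e.g. septation
  thickness, reported merit 0.623) depend on the unavailable patient-level
  values; only the two binary predictors with fully printed counts are
  reconstructible, and those are the ones checked quantitatively.
* With 6 positives among 45, every CV-based quantity has substantial
  fold-assignment variance; all such quantities are therefore averaged
  over seeds and compared as bands, never as point equalities.
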