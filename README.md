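# altscore

Statistical pipeline for separating **benign lipomas (B)** from **atypical
lipomatous tumors (ALT)** using per-patient tables of MRI-derived features.

Benign lipomas and ALT can look nearly identical on MRI, yet ALT recur
locally and need resection, so radiologists want a transparent rule that
flags which lipomatous tumors deserve histological work-up. `altscore`
implements the full analysis chain used to build such a rule from a
two-group feature table (one row per patient, a `group` column with values
`B`/`ALT`, and mixed binary/categorical/continuous feature columns):

1. **Contingency diagnostics** — sensitivity, specificity, PPV, NPV with
   Wilson or Clopper–Pearson intervals, odds ratio with Woolf interval
   (Haldane–Anscombe corrected), positive likelihood ratio
   LR+ = Se/(1−Sp), and a two-sided Fisher exact test computed from the
   hypergeometric distribution with the sum-of-small-p rule.
2. **Two-group comparisons** — Lilliefors normality gate, optional log
   transform, Welch/Student t or Mann–Whitney U; Fisher for categoricals.
3. **ROC dichotomization** — midpoint thresholds, trapezoid AUC (identical
   to the tie-corrected Mann–Whitney statistic U/(n₁n₂)), Youden-index
   cut-off J* = max(Se + Sp − 1) with ALT-protective tie-breaking.
4. **Gain-ratio ranking** — GR = (H(class) − H(class|feature)) / H(feature)
   in bits, cross-validated over 30 seeded folds; features are reported as
   merit mean ± SD and average rank ± SD.
5. **Naive Bayes classification** — smoothed conditional tables
   (pseudo-count α = 0.5), 30-fold CV, with CCR, MAE, weighted TP/FP rates,
   weighted precision and ROC AUC of the pooled out-of-fold posteriors.
6. **The five-item ALT score** — one point each for maximum diameter
   > 125.5 mm, orthogonal diameter > 39.5 mm, septation thickness > 1.3 mm,
   contrast enhancement, and intratumoral STIR fluid signal without
   surrounding fluid; ALT is called at **≥ 3 points**.

Because the underlying patient data are not public, the package ships a
seeded synthetic-cohort generator (`simulate_cohort()`): a latent Gaussian
copula whose per-group marginals are calibrated to the published group
summaries (39 B / 6 ALT; e.g. contrast enhancement 10/39 vs 6/6, maximum
diameter 94.3 ± 49.2 vs 171.2 ± 43.4 mm, septation thickness 0.80 ± 0.45 vs
3.25 ± 2.65 mm, fat fraction 90.2 ± 10.6 vs 73.3 ± 30.3 %).

## Worked example

```r
library(altscore)

cohort <- simulate_cohort(default_cohort_spec(), seed = 42)
fit <- alt_fit(cohort, seed = 42)
fit
#> ALT discrimination pipeline fit
#>   cohort: 45 patients (39 B / 6 ALT), 15 features (9 dichotomized)
#>   top-ranked predictors: stir_discrepancy, sphericity, diameter_x, contrast_enhancement, volume_ml
#> <nb_cv_report> 30-fold CV (seed 42, alpha 0.5)
#>   CCR 100.0% | MAE 0.0029 | TP_avg 100.0% | FP_avg 0.0% | P_avg 100.0% | ROC AUC 1.000
#> <score_report> 5-item score, ROC AUC 1.000
#>   at decision cut-off >= 3: CCR 100.0%, sensitivity 100.0% [61.0 to 100.0], specificity 100.0% [91.0 to 100.0], LR+ Inf
#>   group means: B 0.59 [0.38 to 0.80] | ALT 4.83 [4.40 to 5.26]
```

`fit` carries every intermediate stage: `fit$comparisons` (test used and p
per feature), `fit$cutoffs` (Youden thresholds), `fit$ranking`,
`fit$cv_report` and `fit$score_report`; `coef(fit)` lists the learned score
items, `predict(fit, newdata)` scores new patients and `plot(fit)` draws
the score ROC. Note the synthetic cohort draws features independently
within groups, so classification is easier than on real, correlated
patients — the CCR of 100% above says the pipeline works, not that real
cohorts are this clean.

The diagnostic panel of a published predictor can be recomputed directly
from its 2×2 counts (here STIR discrepancy, in the benign-positive
orientation where "test-positive" means the worrying sign is absent):

```r
tab <- contingency_2x2(37, 2, 1, 5, positive_class = "B",
                       test_positive = "STIR discrepancy absent")
diagnostic_metrics(tab)
#> <diagnostic_metrics> positive class: B | test-positive: STIR discrepancy absent
#>   sensitivity:  94.9% [83.1 to 98.6]
#>   specificity:  83.3% [43.6 to 97.0]
#>   PPV:          97.4% [86.5 to 99.5]
#>   NPV:          71.4% [35.9 to 91.8]
#>   OR: 92.5 [7.04 to 1.22e+03] | LR+: 5.69 | Fisher p: 9.883e-05
```

## Command-line interface

A thin CLI over the same functions ships under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "altscore.R", package = "altscore"))')" \
  simulate --seed 1 --out cohort.csv
# then: analyze, dichotomize, rank, classify, score, pipeline, diag
```
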