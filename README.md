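# neuroprog

Prognostic modelling of combined MRI atrophy and [18F]FDG-PET
hypometabolism in mixed memory-clinic cohorts.

## The problem

Patients referred to a memory clinic under suspicion of neurodegenerative
disease (subjective cognitive decline, mild cognitive impairment or
dementia) typically have several quantitative biomarkers available at
baseline: regional brain volumes from MRI, regional glucose uptake (SUVR)
from FDG-PET, and sometimes CSF total tau. `neuroprog` implements a
reusable, tested pipeline for asking whether *combinations* of these
markers predict clinical progression over one year:

1. **Intracohort z-scores.** Every biomarker x is standardized by the
   cohort's own mean and sample SD, `z = (x − x̄) / s`, computed over the
   subjects non-missing for that variable — no normative population is
   assumed.
2. **Direction-aware dichotomization.** A variable is abnormal when its
   z-score crosses a threshold on the disease side: `z < 0` for volumes and
   SUVRs (atrophy, hypometabolism), `z > 0` for ventricular volume and CSF
   tau. Ties are not abnormal.
3. **Lobe-wise pattern classification.** Each of the 8 unilateral lobes
   ({left, right} × {frontal, temporal, parietal, occipital}) is labelled
   `+A/−H`, `−A/+H`, `+A/+H` or `−A/−H` from its volume and SUVR flags; the
   per-subject counts of the first three patterns (0–8) are dichotomized
   (default: ≥ 2 affected lobes) into exposure predictors. Bilateral
   4-level anatomical variables (no abnormality / isolated atrophy /
   isolated hypometabolism / congruent-or-non-isolated) support an
   exploratory per-lobe model.
4. **Effect estimation.** Univariable odds ratios use the Woolf closed form
   on the 2×2 table, `OR = ad/bc` with `SE(log OR) = √(1/a+1/b+1/c+1/d)`
   and Wald 95% limits `exp(log OR ± 1.96·SE)`; multivariable models are
   maximum-likelihood logistic regressions (IRLS) with mutual adjustment
   plus age and sex, Wald inference from the inverse observed information.
5. **Validation and diagnostics.** Repeated stratified k-fold
   cross-validation (default 10-fold × 1000) with overall and balanced
   accuracy `(sensitivity + specificity)/2`; Belsley condition-number
   multicollinearity diagnostics; a sensitivity grid over z-thresholds
   (0, ±0.1, ±0.5), lobe-count cut-offs (1, 2, 3), outcome definitions
   (clinician rating vs MMSE decline ≥ 3) and diagnosis subgroups.

A synthetic-cohort generator with a latent-severity factor structure, and
fixtures that rebuild subject-level cohorts from published 2×2 contingency
counts, make every stage testable without patient data.

## Worked example

```r
library(neuroprog)
library(dplyr)

cohort <- generate_cohort(synthetic_spec(n = 149, seed = 42)) |>
  collapse_outcome()

z      <- compute_zscores(cohort, c(lobe_volume_roles(), lobe_suvr_roles()))
counts <- classify_lobes(z) |> pattern_counts()
cohort <- cohort |> mutate(
  ah     = dichotomize_count(counts$n_ah),
  a_only = dichotomize_count(counts$n_a_only),
  h_only = dichotomize_count(counts$n_h_only))

model_table(cohort, terms = c("a_only", "h_only", "ah")) |>
  select(term, level, n_stable, n_progressed, or_uni, or_multi, p_multi)
#> # A tibble: 6 × 7
#>   term   level     n_stable n_progressed or_uni or_multi   p_multi
#>   <chr>  <chr>        <int>        <int>  <dbl>    <dbl>     <dbl>
#> 1 a_only unexposed       61           41  NA       NA    NA
#> 2 a_only exposed         25           22   1.31     1.50  0.312
#> 3 h_only unexposed       58           40  NA       NA    NA
#> 4 h_only exposed         28           23   1.19     1.31  0.487
#> 5 ah     unexposed       54           20  NA       NA    NA
#> 6 ah     exposed         32           43   3.63     3.62  0.000279
```

Subjects with the congruent `+A/+H` pattern in two or more lobes have
roughly 3.6-fold higher odds of progressing within a year (this cohort was
simulated with a generating odds ratio of 4.46; the isolated-pattern
predictors carry no generating effect and sit near 1). The univariable
logistic estimate coincides with the Woolf 2×2 closed form:

```r
odds_ratio_woolf(crosstab(cohort, ah))
#>      or conf.low conf.high  p.value method        a     b     c     d
#> 1  3.63     1.82      7.22 0.000239 woolf_2x2    54    20    32    43

glance(repeated_cv(cohort, outcome ~ ah + age + sex,
                   k = 10, repeats = 50, seed = 1))
#>       k repeats     n accuracy balanced_accuracy threshold stratified
#> 1    10      50   149    0.635             0.635       0.5 TRUE
```

Cohort files are read with `read_cohort()` (CSV/TSV, remappable column
schema), descriptive group comparisons come from `baseline_table()` and
`spearman_matrix()`, and `run_sensitivity()` sweeps the whole threshold ×
cut-off × outcome × subgroup grid with structured per-cell failure
reporting. Results objects have `tidy()`, `glance()` and `autoplot()`
methods.

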