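# nodalratio

Hazard-weighted lymph-node ratio staging for censored cancer survival data.

## The problem

The nodal (N) component of TNM staging for esophageal cancer is classically
defined by the count of tumor-involved (positive) regional lymph nodes.
The count of tumor-free (negative) nodes retrieved at lymphadenectomy is
prognostic too, but a raw positive/negative ratio weights the two kinds of
node equally. This package implements a modified N staging that weights each
count by the strength of its fitted effect on survival:

- Fit a multivariate Cox proportional-hazards model for the two node counts
  on a training cohort; let `HR_pln` and `HR_nln` be the per-node hazard
  ratios.
- Form the delta-HR distances from the null point HR = 1:
  `delta_pos = |HR_pln - 1|`, `delta_neg = |HR_nln - 1|`, and the weighting
  coefficient `coef = delta_pos / delta_neg`.
- Score each patient by the re-adjusted N ratio
  `r = coef * n_pln / n_nln`, with zero-count rules: both counts zero gives
  `r = 0`; a single zero count is replaced by 0.0001 before division.
- Choose two stage cutoffs `(c1, c2)` by a minimum-p-value scan: every pair
  of distinct observed ratios is a candidate, each feasible pair is scored
  by the 3-group log-rank p-value, and the minimizing pair wins.
- Stage: `r = 0` is N0, `(0, c1]` N1, `(c1, c2]` N2, above `c2` N3.

The staging model (weights + cutoffs) is derived on a training split,
frozen, and validated on the held-out split by Kaplan-Meier/log-rank and by
ROC comparison against the count-based (AJCC 7th-edition style) N stage,
with stages as ordinal scores against vital status.

A synthetic SEER-like cohort generator with known ground-truth per-node
hazard effects makes the whole pipeline testable without registry access.
Intended users: biostatisticians and cancer-registry methodologists
evaluating nodal staging schemes.

## Worked example

```r
library(nodalratio)

cfg    <- cohort_config(n_patients = 4000, seed = 20)   # SEER-like marginals
cohort <- simulate_cohort(cfg)
kept   <- apply_inclusion_criteria(cohort)$cohort
sp     <- split_cohort(kept, fraction = 0.5, seed = 21)

cv <- crossvalidate_staging(sp$train, sp$validation)
cv$model
#> <nratio_model> trained on 2000 patients
#> <nratio_weights> HR(PLN) = 1.0442, HR(NLN) = 0.9723; delta+ = 0.0442, delta- = 0.0277; coef = 1.59402
#> <stage_cutoffs> N0: ratio = 0 | N1: (0, 1.226e-05] | N2: (1.226e-05, 0.6907] | N3: (0.6907, Inf)
#>   scan: min p = 2.84e-13 over 2305 feasible pairs

tidy(cv)
#> # A tibble: 2 x 7
#>   cohort     chi_square    df  p_value     n n_events n_groups
#>   <chr>           <dbl> <int>    <dbl> <int>    <int>    <int>
#> 1 train            57.8     3 1.70e-12  2000     1234     4
#> 2 validation       86.1     3 1.50e-18  2000     1186     4

roc_compare(dplyr::bind_rows(cv$train, cv$validation))
#> <roc_comparison> AUC modified = 0.573, comparator = 0.535 (outcome: vital
#> status at end of follow-up (censoring time ignored))
```

Reading the output: the training Cox fit estimates a 4.4% hazard increase
per positive node and a 2.8% decrease per negative node, giving a weighting
coefficient of 1.59. The scan places `c1` at the top of the node-negative
cluster (their substituted ratios are of order 1e-4/n_nln, hence the tiny
cutoff) and `c2` at 0.69. Survival separates strongly across the resulting
stages in both the training and the held-out validation split, and the
modified stage orders deaths ahead of survivors better than the count-based
comparator (AUC 0.573 vs 0.535 — modest in absolute terms because this demo
cohort's hazard spread is mild).

`autoplot(cv)` draws the per-stage Kaplan-Meier curves for both splits;
`run_pipeline(pipeline_config(...))` executes the whole flow and writes the
staging-model JSON, scan grid, Cox table, CV report and plots to a run
directory. A thin command-line wrapper lives at `inst/cli/run_pipeline.R`.

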