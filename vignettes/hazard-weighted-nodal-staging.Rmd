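---
title: "Hazard-weighted nodal staging: model, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard-weighted nodal staging: model, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalratio)
```

## The problem

The nodal (N) component of TNM staging for esophageal cancer is
conventionally defined by the count of tumor-involved (positive) regional
lymph nodes alone. But the count of tumor-free (negative) nodes retrieved at
lymphadenectomy also carries prognostic information — it reflects both the
extent of dissection and, indirectly, the extent of regional spread. A raw
ratio of positive to negative counts treats a positive and a negative node
as equally informative, which they are not: in multivariate Cox
proportional-hazards fits, each additional positive node multiplies the
death hazard by roughly 1.06 while each additional negative node multiplies
it by roughly 0.96. The modified staging implemented here weights the two
counts by the strength of their fitted effects before forming a ratio.

## The staging procedure

Let `HR_pln` and `HR_nln` be the multivariate Cox hazard ratios per positive
and per negative node, fit on a training cohort. The procedure is:

1. **Delta-HR distances.** `delta_pos = |HR_pln - 1|` and
   `delta_neg = |HR_nln - 1|` measure each effect's distance from the null
   point HR = 1 (`nratio_delta_hr()`).
2. **Weighting coefficient.** `coef = delta_pos / delta_neg`
   (`nratio_weight()`). When `delta_neg = 0` the negative-node effect is
   indistinguishable from the null and no coefficient exists; this is an
   error, not a silent fallback.
3. **Re-adjusted N ratio.** Per patient,
   `r = coef * n_pln / n_nln` (`readjusted_n_ratio()`), with two zero-count
   rules: if both counts are zero, `r = 0`; if exactly one count is zero, it
   is replaced by 0.0001 before division.
4. **Cutpoint scan.** Two cutoffs `(c1, c2)` on the ratio scale are chosen
   by the minimum-p method (`scan_cutpoints()`): all pairs of distinct
   observed ratio values are candidate cuts, each feasible pair is scored by
   the 3-group log-rank p-value, and the pair with the smallest p wins.
5. **Stage assignment.** `r = 0` is N0; `(0, c1]` is N1; `(c1, c2]` is N2;
   above `c2` is N3 (`assign_stage()`; intervals are left-open,
   right-closed, matching the interval notation in which such cutoffs are
   reported).

Weights and cutoffs are estimated on the training split only and frozen
before the validation split is touched; the serialized staging-model JSON
(`write_staging_model()`) is the unit of transfer.

### The zero-count policy

The literal substitution rule has a counter-intuitive consequence: a
node-negative patient with examined nodes (`n_pln = 0`, `n_nln > 0`) gets a
tiny positive ratio and is staged N1, not N0, while N0 is reserved for
patients with no examined or involved nodes at all. Because this conflicts
with the clinical meaning of N0, both policies are implemented
(`nratio_config(pln_zero_policy = )`): `"literal"` (the default) applies the
substitution exactly as stated; `"clinical"` maps every `n_pln = 0` to ratio
0 and hence N0. The default follows the published rule; the evaluation
section below explains where the clinical policy is the right experimental
design.

## The cutpoint scan in detail

- **Candidate grid.** Candidates are the distinct observed ratios of staged
  patients (ratio > 0); patients at ratio 0 are fixed N0 and excluded from
  the scan. Using observed values rather than an arbitrary numeric grid
  matches how optimal-cutpoint tools behave. When there are more than
  `max_cutpoints` (default 100) distinct values, the candidate set is
  thinned to an evenly spaced subset of the observed values; the scan is
  quadratic in the number of candidates, and registry-scale cohorts carry
  thousands of distinct ratios. Below the cap the grid is exactly the
  distinct observed values.
- **Feasibility.** Each of the three groups must contain at least
  `min_group_frac` (default 5%) of the staged patients, a standard guard
  against cutpoints that isolate a handful of extreme values. If no pair is
  feasible the scan fails with the tightest achievable fraction in the
  error message.
- **Tie-breaking.** Among pairs whose p-values agree within 1e-12, the pair
  maximizing the smallest group, then the lexicographically smallest
  `(c1, c2)`, is chosen — this makes the scan deterministic.
- **Multiple testing.** The selected minimum p is reported raw, as is
  conventional for this procedure. A Miller-Siegmund-corrected p is reported
  alongside for information; the correction is derived for a single-cutpoint
  scan and is applied at `min_group_frac`, so for the two-cutpoint scan it
  is an informational approximation, not an exact size correction.
- **Internals.** The scan evaluates the 3-group log-rank statistic from
  prefix-cumulated event and at-risk matrices over the candidate grid, so
  each pair costs a handful of vector operations over the distinct event
  times. Unit tests verify exact agreement with an exhaustive double loop
  over all pairs using the general `logrank_test()`.

## Survival primitives

`km_estimate()` and `logrank_test()` are implemented in the package (they
sit inside the scan's hot loop and its brute-force test oracle);
`logrank_test()` is verified against `survival::survdiff()` in the test
suite. `fit_cox()` wraps `survival::coxph()` with the Efron treatment of
tied event times — survival is recorded in whole months, so ties are heavy —
Newton-Raphson with coefficient tolerance 1e-9 and at most 100 iterations,
and Wald confidence intervals and p-values (the output layout typical of the
statistical packages used for such analyses). Likelihood-ratio statistics
are available from the underlying fit but are not the default report.
Covariates that are constant in the cohort are flagged `non_identifiable`
rather than silently dropped. When the log-rank variance matrix is singular
(identical groups with no variation), a pseudo-inverse yields the degenerate
statistic 0 instead of an error.

## The synthetic cohort generator

`simulate_cohort()` emulates a registry extract of resected
esophageal-cancer patients so that the whole pipeline is testable without
external data. Defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `mean_age`, `sd_age` | 66.70, 11.12 years | age, normal |
| `prop_male` | 0.799 | sex ratio |
| `race_props` | 84.9 / 10.1 / 4.7 (renormalized) | white / black / other |
| `mean_tumor_size`, `sd_tumor_size` | 366.58, 179.92 units | registry size code, normal truncated at 1 |
| `nln_mean`, `nln_dispersion` | 12, 2 | negative nodes, negative binomial |
| `pln_zero_prob`, `pln_mean`, `pln_dispersion` | 0.45, 2.8, 1.2 | positive nodes, zero-inflated negative binomial |
| `log_hr_per_pln`, `log_hr_per_nln` | log(1.064), log(0.962) | ground-truth per-node effects |
| `baseline_median_months` | 10 | baseline survival, Weibull (`weibull_shape = 1`, exponential) |
| `admin_censor_months` | 96 | administrative horizon (an eight-year registry window) |
| `target_event_frac` | 0.605 | realised death fraction |

Node counts use negative binomial families because nodal yields are
overdispersed relative to Poisson; the zero inflation reflects the large
node-negative fraction of resected cohorts. No published distributions exist
for these counts, so the dispersion and zero-probability values were chosen
once as clinically plausible and are exposed as parameters.

Censoring combines the administrative horizon with uniform loss to
follow-up whose scale is calibrated by root-finding *on the generated
sample* so the realised event fraction matches `target_event_frac`; the
calibration is deterministic given the draws, so a fixed seed reproduces
the cohort byte for byte. Times are recorded as whole months (ceiling,
minimum 1), which produces the heavy ties the Efron correction is for.

`hazard_model = "nodes"` (default) makes the log-hazard linear in the two
node counts — the data-generating mechanism matching the Cox model that the
weighting step fits. `hazard_model = "ratio"` instead drives the log-hazard
by `log_hr_per_ratio * log1p(r)` where `r` is the true weighted ratio; the
`log1p` transform keeps the linear predictor bounded when `n_nln` is small
(raw ratios reach the hundreds). This mode generates cohorts in which the
ratio, not the raw counts, is the prognostic truth.

What the generator does **not** emulate: the joint covariate structure of a
real registry (covariates are drawn independently), treatment-sequence
effects, histology subtypes, or any dependence of censoring on covariates.
Passing tests therefore demonstrate correctness of the procedure under a
proportional-hazards truth with known effects — not that the modified
staging is clinically superior on real data.

## Evaluation design

- **Split.** `split_cohort()` defaults to an exact 50/50 partition
  (published train/validation sizes of near-equal halves imply exact
  randomization); Bernoulli assignment is available.
- **Cross-validation isolation.** `crossvalidate_staging()` fits everything
  on the training split; tests assert that mutating every validation outcome
  leaves the serialized staging model byte-identical.
- **ROC convention.** Stages enter as ordinal scores 0-3 against vital
  status at end of follow-up, ignoring censoring times — the conventional
  fixed-endpoint ROC used to compare staging systems; a time-dependent AUC
  is deliberately out of scope. The trapezoidal AUC with midpoint tie
  handling equals the rank-sum (concordance) estimator, which tests verify
  by exhaustive pair enumeration and against `pROC`. Every report states
  the outcome convention.
- **Directional superiority experiment.** On ratio-driven cohorts
  (`hazard_model = "ratio"`), the modified stage should out-rank the
  count-based comparator. This experiment uses the *clinical* zero policy:
  under the literal rule the modified system collapses the ~45%
  node-negative mass into N1 while the comparator resolves it as a separate
  N0 level below N1, and that granularity difference — four informative
  levels against three — costs the modified system more AUC than the ratio
  ordering gains, regardless of how strong the ratio signal is. With the
  clinical policy both systems share the node-negative N0 boundary and the
  comparison isolates what is actually at issue: whether the weighted ratio
  orders node-positive patients better than the positive-node count alone.

## Problem sizes and numerical choices

The test suites run at sizes chosen to keep Monte-Carlo error well inside
the asserted tolerances: marginal calibration at n = 10,000; Cox recovery at
n = 5,000 plus 100 replicates of n = 1,000 for confidence-interval coverage;
scan-oracle equivalence on 50 cohorts of 60-200 patients (below the
candidate cap, so the grid is exact); cross-validated significance on 50
replicates of 4,000 + 4,000 with per-node HRs 1.15 / 0.93 ("strong" effects
— the default printed HRs also separate at this n, these just make the
replicate criterion unambiguous); ROC directionality on 100 replicates of
n = 4,000. The log-rank null-calibration study uses 300 subjects per group
because the chi-square approximation to the log-rank statistic itself runs
slightly anti-conservative below roughly 100 events per group (empirical
level ~0.054 at 100 per group, ~0.051 at 300, measured with
`survival::survdiff` as the reference); the calibration claim is about the
implementation in its asymptotic regime, not about small-sample exactness.

Numerical details worth knowing: hazard ratios are `exp(coefficient)` by
construction; the scan treats p-ties within 1e-12 as exact ties; variance
terms at event times with fewer than two subjects at risk are zero; the
`uniroot` censoring calibration runs on (1e-9, 1e9) with tolerance 1e-10
and falls back to administrative censoring only when even uncensored
follow-up cannot reach the target event fraction.

## Known limitations

- The Miller-Siegmund correction is approximate for a two-cutpoint scan (see
  above); the raw minimum p is the primary report, as in the original
  procedure.
- The generator's covariates are mutually independent; effects other than
  the node counts default to zero. Table-style multivariate fits are
  exercised, but confounding structures are not simulated.
- The ROC ignores censoring time; with heavy differential censoring a
  fixed-endpoint AUC can mislead. The convention is stated in every report.
- Ratios are undefined for records with missing node counts; such records
  should be removed by `apply_inclusion_criteria()` before staging.
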