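---
title: "Survival trees and accuracy indices for cardiovascular risk stratification in hemodialysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival trees and accuracy indices for cardiovascular risk stratification in hemodialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrisktree)
```

## The problem

Patients with end-stage renal disease on hemodialysis carry an extreme
and heterogeneous risk of major adverse cardiovascular events (MACE:
cardiovascular death, non-fatal myocardial infarction or non-fatal
stroke). Single circulating biomarkers — including plasma microRNAs
quantified by RT-qPCR — often show weak marginal association with the
endpoint in unselected cohorts, yet can still carve out clinically
distinct subgroups when allowed to interact with clinical covariates.
`hdrisktree` implements that analysis end to end: a survival-CART model
whose splits are chosen by weighted log-rank statistics, bagging for
variable selection and honest error measurement, and two accuracy
indices for the resulting ordinal risk partition — the integrated
cumulative/dynamic AUC (iAUC) and an incidence-rate variation index
(IRV).

## The synthetic cohort generator

Individual-level dialysis trial data are not public, so the package
ships a first-class generator (`tree_spec()`, `generate_cohort()`) that
emulates the latent structure such an analysis targets:

* a full binary risk tree of depth 3 with eight leaves (binary-heap node
  ids 8–15). The default splits: age at 64 years at the root; history of
  diabetes on the younger branch; hsCRP at 3.221 mg/L (younger,
  non-diabetic) and miR-632 at 2.850 log10 units (younger, diabetic);
  hsCRP at 0.827 mg/L on the older branch, then miR-186-5p (its marginal
  median, 4.5 — no external anchor exists for this cutoff) and history
  of CVD. The variable splitting the older/high-hsCRP side is likewise
  not externally anchored; history of CVD was chosen as the remaining
  risk-score component.
* one incidence rate per leaf, defaults 6.33, 21.17, 23.66, 101.57,
  13.21, 25.75, 31.28, 79.40 events per 100 patient-years for leaves
  8–15. Only the low-risk (node 8) and high-risk (node 11) anchors are
  fixed by the motivating analysis; the middle assignment is a
  configurable convention.
* event times exponential within leaf with hazard `leaf_ir/100` per
  patient-year, so the events/person-time estimator is unbiased for the
  leaf rate — a closed-form recovery target used by the tests.
* independent censoring: the minimum of a 5-year administrative horizon
  and exponential dropout at 0.19/year, giving a mean event-free
  follow-up of about 3.2 years.
* covariate marginals typical of a dialysis trial population aged
  50–80: age uniform on (50, 80); hsCRP log-normal (median 3 mg/L);
  miRNA levels normal on the log10 scale; miR-210-3p carries a
  log-hsCRP component so that it can act as a surrogate for
  inflammation in fitted trees.
* matched (greedy nearest-neighbour on standardized covariates, 1:1,
  with pair identifiers) or simple random case/control draws, and MCAR
  missingness restricted to KT/V, BMI, albumin and hsCRP — the pattern
  seen in the validation-phase data the pipeline is built for.

What the generator does **not** emulate: the joint dependence of the
clinical covariates beyond the latent tree, informative censoring,
batch structure in the qPCR measurements, or treatment effects. Tests
passing on these cohorts therefore certify the estimators and the
recovery machinery, not performance on any real cohort.

Follow-up is stored in months throughout; incidence rates are always
reported per 100 patient-years, with the months-to-years conversion in
exactly one internal helper.

## qPCR preprocessing

`normalize_dcq()` implements the delta-Cq method against the
miR-486-5p internal reference: `level = -(Cq - Cq_ref) * log10(2)`,
i.e. log10 of `2^-dCq`. Samples with Cq at or above 35 cycles are
flagged undetected and `floor_censor()` replaces their level by the
minimum detected level of the same miRNA; an assay with no detected
sample is refused (such assays are discarded upstream). The relation
between this scale and any external "arbitrary units" scale is an
additive offset on the log10 scale, configurable and 0 by default; the
synthetic generator produces levels directly on the analysis scale.
`binarize()` provides the three binary codings (above first tertile,
median, second tertile) with type-7 empirical quantiles and a strict
inequality — ties at the cutoff code low.

## The split statistic and the tree

`grho_statistic()` is the Harrington–Fleming G^rho class: at each
distinct event time the observed-minus-expected event count of one
group (hypergeometric expectation and variance from the 2×2 risk-set
table) is weighted by the pooled Kaplan–Meier survival just before that
time raised to rho. rho = 0 — the package default — is the ordinary
log-rank test; larger rho up-weights early differences. The
implementation is validated in the tests against an independent naive
summation and against `survival::survdiff()`.

`fit_tree()` grows the tree recursively. Per node, each continuous
predictor is scanned at midpoints between consecutive distinct values
(capped at 100 evenly spaced candidates; the scan is exhaustive below
the cap), categorical predictors at all binary level partitions (at
most 8 levels). The admissible split maximizing the statistic wins;
ties go to the lowest cutoff. Stopping: depth 3 (at most eight leaves,
mirroring the target tree), minimum node size 20, and a minimum split
chi-square of 3.84 — the 5% critical value of a 1-df chi-square. No
cost-complexity pruning is applied. Note that 3.84 is calibrated for a
single pre-specified cutpoint: a continuous variable scanned at many
cutpoints faces a maximally selected statistic and will cross 3.84 under
the null far more than 5% of the time. The null-behaviour tests
therefore use binary noise predictors, for which the nominal level
holds; users who need family-wise control should raise
`min_split_stat`.

Surrogate splits are CART-style: for every other numeric predictor, the
cutoff (and direction) maximizing agreement with the primary
left/right assignment among observations non-missing on both; kept only
if it beats the majority-direction baseline, ordered by agreement, at
most five per node. Missing split values are routed by the first
applicable surrogate, then by the majority direction, so children
always partition the parent exactly.

Leaves are ranked by decreasing incidence rate (ties broken by larger
event count) — the ordinal risk hierarchization. `node_summaries()`
reports per-leaf n, events, person-years, IR, the Kaplan–Meier curve,
and the Cox hazard ratio against the lowest-IR leaf (reference choice:
the least-risky leaf, so all HRs are at least about 1).

## Bagging

`run_bagging()` draws bootstrap resamples of whole patients, fits a
tree to each, and aggregates: selection frequency (fraction of
iterations using the variable in a primary split), surrogate-aware
importance (each split's chi-square credited in full to the primary
variable and as chi-square × agreement to each kept surrogate; averaged
over iterations and normalized so the top variable scores 100), the
out-of-bag error (one minus the iAUC of each patient's average
out-of-bag leaf-IR prediction), and percentile confidence intervals
(type-7 quantiles at 2.5/97.5%) for the iAUC and IRV of the
bootstrap-fitted trees. A single-leaf iteration contributes zero
selections, not an error. Every iteration's seed derives from the
master seed, so a report is reproducible end to end. The surrogate
credit is what lets a variable that is never selected — because a
correlated competitor is chosen first — still show high importance; the
acceptance tests demonstrate this with an exact duplicate predictor.

## Accuracy indices

`cd_auc()` is the cumulative/dynamic time-dependent AUC with inverse
probability of censoring weighting: cases are subjects with events by
t (weight `1/G(T_i-)`), controls subjects event-free past t (weight
`1/G(t)`), with G the Kaplan–Meier estimate of the censoring
distribution and ties in the score counting one half. Without censoring
it reduces exactly to the Mann–Whitney AUC of the dichotomized outcome,
which is how it is cross-checked. `integrated_auc()` averages AUC(t)
over the grid by the trapezoid rule with uniform weight in t, up to a
horizon (a 24-month horizon probes early discrimination; the default is
the end of follow-up).

The default evaluation grid (`time_roc()`) uses distinct event times
but only where both the cumulative-case and dynamic-control sets
retain at least 20% of the sample (floor of 20 subjects), thinned to at
most 50 points. This stability truncation keeps the estimator's null
sampling error within about ±0.05 at n = 2000 — without it, AUC(t) at
the extremes of follow-up is dominated by a handful of subjects, as is
well known for IPCW time-dependent ROC estimators.

`irv_index()` summarizes the heterogeneity of leaf incidence rates
around the pooled rate. The exact published form of this index is not
recoverable from its source, so the definition is pluggable and always
reported with its identifier:

* `wtd_abs_dev` (default): `sum_i (n_i/n) |IR_i - IR|`, in IR units
  (per 100 patient-years) — uses exactly the named ingredients (pooled
  IR, leaf IR_i, leaf size n_i);
* `wtd_sd`: size-weighted standard deviation of the leaf rates;
* `cv`: `wtd_sd / IR`, dimensionless.

All three are zero exactly when the leaves are homogeneous, invariant
to leaf order, and (for the first two) scale linearly with a common
rescaling of the rates.

## Cox layer and missing data

`fit_cox()` fits the per-biomarker Cox proportional-hazards model
(Efron tie handling, Wald 95% intervals), continuous or dichotomized,
under three strategies for missing adjustment covariates:
complete-case, median imputation, and chained-equation multiple
imputation. The chained equations use predictive mean matching
(approximate Bayesian parameter draws, five donors, 10 sweeps) with the
outcome entering the imputation model as the event indicator and
log-time; 100 completed datasets by default, pooled by Rubin's rules
with Barnard–Rubin style degrees of freedom. With no missing values
the imputation is the identity and the pooled fit reproduces the
complete-case fit — a degeneracy the tests assert to three decimals.

## Numerical conventions

* Quantiles everywhere are type-7 (linear interpolation); binary
  codings use strict "greater than".
* Split ties break to the lowest cutoff, then to the earlier predictor
  in the supplied list; surrogate ties keep the higher agreement first.
* All randomness flows from explicit integer seeds; multi-stage runs
  derive per-stage seeds from one master seed by a fixed counter
  scheme, so stages are reproducible independently.
* Degenerate inputs (no events, constant predictors, empty classes,
  leaves with zero person-time, assays never detected) are rejected
  with messages naming the offending quantity rather than propagating
  NaNs.

## Problem sizes in the shipped tests

The test-suite simulations use cohorts of 200–4000 patients for tree
behaviour (20 seeds for structure recovery, 100 replicates for null
calibration), 20,000 per rate for incidence-rate recovery, 100–200
bootstrap iterations for bagging behaviour, and 50–100 replicates for
the Cox calibration checks; these sizes give the Monte-Carlo margins
stated in each test while keeping the default run a few minutes long.
A full analysis would typically use 1000 bagging iterations, as
`run_bagging()`'s default documents.

## Known limitations

* Surrogate splits are searched among numeric and logical predictors
  only; categorical predictors can be primary splitters but not
  surrogates.
* The split-statistic threshold is per-cutpoint, not family-wise (see
  above); there is no pruning.
* The iAUC integrates with uniform weight in time; alternative
  weightings (e.g. by event density) are not implemented.
* The phase-I matched-pair structure is used for sampling and baseline
  tables but the Cox layer adjusts for the matching variables rather
  than stratifying on pairs.
* No competing risks, time-varying covariates, or incident/dynamic ROC
  variants.
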