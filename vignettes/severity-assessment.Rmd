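---
title: "Methods: explainable DASS-42 severity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable DASS-42 severity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dassxdt)
```

This vignette is the package's account of its methods: the scoring and
banding model, the query-elimination rule, the balanced decision tree,
the reasoning engine, the synthetic generator the tests rely on, and
the numerical choices made where the design was genuinely open.

## Scoring model and assumptions

Each DASS-42 respondent answers 42 ordinal items coded 1–4; subtracting
one gives rate points on the 0–3 scale. The items partition into three
fixed 14-item subscales (anxiety, stress, depression), and a
respondent's Weight Score for a disorder is the plain sum of its 14
rate points, an integer in [0, 42]. Severity is a pure banding of WS:

| level | anxiety | stress | depression |
|-------|---------|--------|------------|
| N     | 0–7     | 0–14   | 0–9        |
| M     | 8–9     | 15–18  | 10–13      |
| MD    | 10–14   | 19–25  | 14–20      |
| S     | 15–19   | 26–33  | 21–27      |
| ES    | 20+     | 33+    | 28+        |

The stress S and ES bands overlap at WS = 33 as printed; we resolve any
boundary overlap by giving the more severe band precedence, so 33 is
labeled ES. This precedence rule, not a band edit, is the package's
resolution of the inconsistency: it keeps the published intervals
verbatim while making the label a total function of WS. With it, every
integer WS in [0, 42] receives exactly one label and the label is
monotone non-decreasing in WS — both enforced by tests.

Two smaller conventions in the encode step: cells that are absent,
non-integer, or outside 1–4 count as missing and are imputed with the
column mode *on the raw codes, before rescaling* (imputation and
encoding commute here, but imputing first keeps the mode on the scale
the respondent actually used); modal ties break deterministically to
the smallest value, so reruns are bit-identical.

## Q-Prioritization

A query's priority relevance is its mean rate point over respondents,
and a query is eliminated when that mean is *at or below* the
disorder's relevance threshold. The defining ratio
`R_th = Normal_max / (Count_col × Rate_max)` is available through
`compute_rth()`, but no single choice of `Rate_max` reproduces all
three published constants (0.5, 1.0, 0.2) from `Normal_max` = 7, 14, 9
and 14 columns, so the constants themselves are the defaults carried on
each disorder set, and the ratio stays available for user-derived
thresholds. Three further choices:

* **Equality drops.** At `P^rel = R_th` the query is dropped; the
  elimination branch wins the overlap.
* **Ranking direction.** Survivors are reported in ascending-mean order
  (least relevant first), with a descending rank alongside, so both
  readings of "priority order" are serialized.
* **Guard.** If a threshold would eliminate every query the step
  refuses, keeps all, and warns — an empty questionnaire is never a
  useful outcome.

On the bundled ten-volunteer cohort the anxiety and stress thresholds
eliminate exactly Q9 (mean 0.4) and Q18 (mean 0.8); the depression
threshold of 0.2 eliminates nothing, because every depression item's
mean (minimum 0.5, item Q16) clears it. We follow the rule, not any
particular narrative of which item "should" drop.

## Balanced decision tree

The base learner is a decision tree over the rate-point grid with
*multiway categorical splits*: a node splits on the attribute of
maximal information gain, with one branch per observed value 0–3, each
root-to-leaf path testing an attribute at most once. Gains tie-break to
the lowest-indexed query and branches are ordered by value, so
induction is deterministic. Stopping is by purity, exhausted
attributes, or node size at or below `min_leaf` (default 1); there is
no pruning. Prediction descends by attribute value and falls back to
the current node's majority label when a value was never seen there;
fractional inputs (from counterfactual search) are rounded onto the
grid first.

The *balanced* wrapper addresses severity imbalance. We interpret the
sampling rate `S` as the target minority:majority count ratio: at rate
`S`, every class below `S × majority` is topped up to
`ceiling(S × majority)` by drawing its own rows with replacement, and
the majority class is never touched. The loop escalates
`S = 0.1, 0.2, …, 1.0`, growing a tree per round and scoring it on a
stratified 20% holdout that is split off *before* any oversampling (so
replicated rows never leak into validation). Starting from a reference
accuracy of zero, the loop keeps the best round and stops at the first
round whose accuracy falls strictly below the best so far, or after
rate 1.0. Accuracy for the loop is validation accuracy: training
accuracy cannot decrease under replication, so it could never trigger
the stopping rule. All randomness flows from one recorded seed; every
round's rate, accuracy and post-sampling class counts are kept in the
model's trace, and models serialize to plain JSON.

## Reasoning engine

*Permutation importance.* A query's P-score is the base accuracy minus
the mean accuracy over `repeats` (default 10) independent uniform
shuffles of its column. Constant columns get an exact zero, since any
permutation is the identity on them. Scores are procedure-defined, not
calibrated to any external magnitudes.

*Pertinent positives.* The PP set is a locally minimal set of queries
such that masking everything outside it to the baseline value still
yields the original label. The baseline is 0 — the "did not apply to
me" response — and is reported with the explanation. Backward greedy
elimination tries to remove queries closest to baseline first; a
leave-one-out pass verifies that removing any single survivor changes
the prediction, which the tests re-check by construction.

*Pertinent negatives.* The PN search enumerates value substitutions on
the 0–3 grid by increasing cardinality up to a budget (default 3) and
returns the first set that flips the label, with its flipping values
and the new label; exhausting the budget returns an explicit not-found
result rather than an error. Every returned PN re-predicts to its
reported flip.

*Counterfactuals.* A counterfactual perturbation δ minimizes
`x·L_pred + β·‖δ‖₁ + ‖δ‖₂²`, where `L_pred` is a hinge (margin 0) on
the difference between the best non-target class probability and the
target probability at the reached leaf. Because tree probabilities are
piecewise constant, plain descent from the instance stalls whenever no
single-coordinate move crosses a split, so the search instead starts at
the target-class *prototype* — the per-query mean of reference rows
with the target label — and pulls coordinates back toward the instance
in order of prototype distance, over a 0.25-spaced value grid (deltas
may therefore be fractional). When the regularizers dominate the hinge,
the unconstrained minimum is "abandon the flip"; in that case the
prediction weight doubles (from its default `x = 1`, at most 13 times)
until the target label holds, and the final weight is reported as
`x_used`. Accepted moves never increase the loss, negative deltas read
as "reduce this behaviour", and the L1 weight β (default 0.1) controls
sparsity — raising it never adds nonzero deltas on the fixtures the
tests sweep.

*Feedback.* Prose is template-driven (YAML: clause templates plus short
per-item phrases), keyed by the PP/PN sets and counterfactual deltas,
so every query cited in the text is traceable to an explanation object.

## Synthetic generator

`generate_responses()` emulates the shape of DASS-42 response matrices:
per respondent and disorder a severity band is drawn from a mixture
(default 0.3/0.2/0.2/0.2/0.1 over N/M/MD/S/ES), and the 14 rate points
are drawn uniformly from all tuples whose sum lies in that band's
interval. Uniform-within-band sampling is implemented *exactly* via
composition counts: the number of j-item tuples summing to s is
tabulated once, the row sum is drawn with those weights restricted to
the band, and cells are filled sequentially with
remaining-count-proportional probabilities. This is distributionally
identical to rejection from uniform cells but has no rejection cost —
relevant because extreme bands are astronomically rare under uniform
cells (the anxiety Normal band, sums 0–7 of 14 items, has acceptance
around 6×10⁻⁴). Designated "irrelevant" queries are overwritten with a
fixed low-mean distribution (P(0,1,2,3) = .7/.2/.08/.02) independent of
class; symmetric ±1 noise (default rate 0.05) is applied cell-wise with
clipping; ground-truth labels are then *re-derived* from the final rate
points, so truth always agrees with the scoring rules even under noise.
The three disorders are generated independently.

What the generator does **not** emulate: inter-item and inter-disorder
correlation (real DASS items are driven by a shared latent severity and
are strongly positively correlated), item-specific difficulty, and
response styles. Uniform-within-band sampling is in fact close to a
worst case for tree learners — conditioning a maximum-entropy item
distribution on a sum band leaves almost no low-order structure — so
accuracies measured on this generator are conservative relative to real
questionnaire data, where correlated items make severity far easier to
recover. Passing pipeline tests on this generator demonstrates contract
correctness (determinism, band membership, loop behaviour, explanation
re-prediction), not clinical-grade accuracy.

## Problem sizes and runtime choices

The test and reproduction scripts use cohorts of 2,000 respondents for
training-loop properties (with a 0.6/0.2/0.1/0.07/0.03 mixture and 5%
noise for the imbalanced setting), 5,000 for mixture-convergence
checks, and 200–400 for explanation contracts; the brute-force
entropy/gain sweep uses 300 random tables of at most 8 rows, 3
attributes and 3 classes at tolerance 1e-12. These sizes give stable
means (ten seeds for the balanced-vs-plain comparison) while keeping a
full run in well under a minute of tree induction.

## Known limitations

* A single axis-aligned tree — balanced or not — approximates a
  sum-of-14 band boundary poorly on the uncorrelated generator above;
  the reproduction script reports the measured balanced, plain and
  noise-free holdout accuracies rather than asserting any headline
  figure. The balanced wrapper's value shows up as the *difference*
  against the plain tree under imbalance, which is what the comparison
  harness measures.
* PN search is exhaustive within its budget and so exponential in it;
  budgets above 3 on 14 queries get slow.
* Counterfactual search is heuristic coordinate descent; it is exact on
  depth-1 trees but only best-effort (flagged `converged = FALSE`) on
  general trees.
* Severity bands are configuration, not inference: the package labels
  by the published cutoffs and makes no clinical claim.
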