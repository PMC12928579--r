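---
title: "Auditing clinical classifiers for fairness and robustness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing clinical classifiers for fairness and robustness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Machine-learning classifiers for Parkinson's disease (PD) are trained on
cohorts whose demographics are skewed: cases are more often male, most
participants are 60 or older, and White participants dominate. A model fitted
to such data can be accurate on average yet systematically unequal across
demographic groups, and its training data can be tampered with — labels
flipped, or a proxy for a sensitive attribute smuggled into the features —
in ways that degrade both utility and equity. `fairaudit` packages the whole
audit loop: simulate a PD-like case/control cohort, prepare it
deterministically, train standard baselines, measure group fairness, learn a
pre-processing mitigation, attack the training data, and report everything
with repeated-run statistics.

## The synthetic cohort generator

The generator emulates the structure of a baseline visit of a PD
case/control study. Its defaults *are* the audited study conditions and are
not adjusted per experiment:

* 648 cases and 434 controls (exact allocation);
* 391 males among cases, 202 among controls (exact allocation);
* ages from Gaussians with case/control means 64.23 / 62.83 years,
  sd 9 years, truncated to [30, 95] (the study reports only the means; 9
  years is a typical dispersion for a PD cohort and the truncation keeps
  ages clinically plausible);
* race assigned White to 90% of participants (exact allocation; the source
  reports "overrepresentation" without a count, so the fraction is a
  configurable default chosen to be clearly skewed);
* thirteen clinical features (smell identification, semantic fluency,
  REM-sleep behaviour, sleepiness, cognition, depression, the three motor
  subscales, Hoehn & Yahr stage, daily-living ability, fatigue, education)
  drawn from group-conditional Gaussians with the published case/control
  means. The published table's dispersion column is treated as a
  within-group sd (its semantics are not stated), floored at 0.1 so every
  feature keeps spread;
* optional missing cells, completely at random, per feature
  (`missing_frac`; the mechanism is a modelling choice — no mechanism is
  stated for the real data);
* optional planted outcome bias: `bias_strength` sets the label base-rate
  gap between the unprivileged and privileged bins of one sensitive
  attribute, realized by exact counting. When the generator plants bias it
  also redraws the clinical features of re-labelled rows from the new
  class's distribution, so the planted disparity links *groups to label
  rates* rather than injecting feature-independent label noise. The
  standalone `plant_outcome_bias()` is a pure relabeling operation (useful
  when label noise is exactly what you want) — the distinction matters for
  prediction-level audits.

What the generator deliberately does **not** emulate: longitudinal visits,
inter-feature correlation beyond group-conditional means, informative
missingness, and any relationship between sensitive attributes and clinical
features within a class. Passing tests on this cohort therefore validate the
pipeline's mechanics and contracts, not clinical claims about real PD data —
on real data the features correlate with each other and with demographics,
and effects such as leakage-proxy importance are stronger than they appear
here.

## Preprocessing

The order is fixed: cleaning (exact-duplicate removal, text-to-number
repair), the missingness filter (a clinical feature is dropped only when
*strictly more* than 30% is missing), split-plan creation, median/mode
imputation, min–max normalization `y' = (y - y_min)/(y_max - y_min) * (d - c) + c`
onto [0, 1], and sensitive-attribute binarization. Every fitted statistic
(median, mode, `y_min`, `y_max`) uses training rows only and is then applied
everywhere; held-out values outside the fitted range are clipped to the
interval and counted. `fit_scope = "all"` reproduces the laxer reading in
which statistics see all rows; the default avoids test leakage. Ties in the
imputation mode break to the smallest value, and a constant feature maps to
`c` — both pure determinism choices. Splits are stratified by label (20%
held out per class, five CV folds balanced to ±1 row).

Binarization rules: age is cut at 60 years (the cohort's own clinical
stratification point), race at White / Non-White, gender is already 0/1
(1 = male). Privileged designations default to the majority bins (<60,
White, male) and are configurable; every signed metric records the
convention.

## Feature selection

Two stages, both fitted on training rows only and never on sensitive
columns: (1) a SULOV-style filter removes, from every pair with |Pearson
correlation| > 0.70, the member with lower mutual information with the label
(greedy, highest correlation first; ties keep the earlier column);
(2) recursive importance ranking fits a gradient-boosted ensemble (xgboost,
single thread), ranks by gain, keeps the top 75%, and repeats up to 3 rounds
or until stable. Because rounds are nested, the final set equals the
features retained in every round. The source states neither the correlation
ceiling, the keep fraction, nor the round count; these defaults are exposed
as arguments.

## Fairness metrics

Per-group confusion counts feed the eight rates (TPR, TNR, FPR, FNR, FDR,
FOR, PPV, NPV) and the four bias metrics: statistical parity difference,
disparate impact, equal opportunity difference, and average absolute odds
difference. Conventions:

* signed metrics are **unprivileged minus privileged** (so a negative SPD
  means the unprivileged group receives fewer positive predictions);
* a zero denominator yields `NA` — an explicit undefined marker, never a
  silent 0; aggregation skips and counts them;
* AAOD's defining formula is a nonnegative magnitude, yet signed values are
  routinely reported; the package returns
  `sign(dTPR) * (|dFPR| + |dTPR|)/2` with the pure magnitude attached as an
  attribute, reconciling the formula with signed reporting.

All metrics are checked against an independent brute-force recount oracle
on 1,000 random prediction/label/group triples, along with the exact
algebraic identities (TPR + FNR = 1, DI = 1 + SPD/P(pred = 1|priv),
privileged-swap antisymmetry).

## Optimized pre-processing mitigation

The mitigation learns a conditional distribution
`p(x̂, ŷ | x, y, s)` over a discretized feature space and the binary label,
minimizing expected distortion subject to three constraints:

1. **group fairness** — the transformed label-rate gap
   `|P(ŷ=1|s=0) − P(ŷ=1|s=1)|` is at most `eps_fairness` (default 0.05);
2. **individual distortion** — expected distortion within every
   `(x, y, s)` conditioning is at most `distortion_budget` (default 0.5),
   with distortion = per-feature Hamming distance on bins plus weight 2 per
   label flip;
3. **fidelity** — total-variation distance between the transformed and
   original `(x, y)` marginals is at most `fidelity_budget` (default 0.1).

This is a linear program over the transition probabilities. The feature
space is the product of quantile bins over the two features most informative
about the label (3 bins each by default). Keeping the mapped space small is
what makes the LP desk-sized (≈ 670 variables, well under a second per
solve) while the remaining features pass through untouched; widening to more
features or bins grows the variable count geometrically and is exposed as
configuration for users with stronger solvers.

Numerically, the LP is solved as a vanishing-ridge quadratic program
(`min c'x + λ/2‖x‖²`, λ = 1e-8) with quadprog's dual active-set method,
which returns the least-norm point of the optimal face and is robust on the
LP's highly degenerate constraint structure; a plain dense simplex was
observed to hit exactly singular bases on these instances. A zero distortion
budget pins the map at the identity, which is decided arithmetically rather
than handed to the solver. Infeasible constraint sets are reported together
with the minimal feasible `eps_fairness` found by bisection.

Two readings of "post-mitigation disparity" exist: the *implied*
(distribution-level) gap, computed exactly from the fitted map, and the
*empirical* gap of one sampled application, which carries binomial noise of
order 0.03 at a thousand rows. The fairness constraint governs the implied
gap, so recovery checks assert it at solver tolerance (1e-4); the sampled
application is checked separately to converge to the implied rates (three
standard errors at n = 50,000). Application keeps raw values whenever the
sampled cell equals the original cell, so the identity map leaves rows
byte-identical; changed bins are realized as the destination bin's median.
Mitigation is strictly pre-processing: it is fitted on and applied to
training rows only, and the harness asserts held-out rows pass through
untouched.

The LP implementation is verified against an exhaustive lattice oracle on a
2-cell × 2-label × 2-group toy whose optimum lies exactly on a 0.25-step
probability lattice (≈ 1.5 million candidate transformations per group).

## Adversarial attacks

**Label poisoning** flips `y ← 1 − y` for a configured fraction of
*training* labels (main rate 5%; sensitivity sweep 0–20%), chosen uniformly
within class × sensitive-group strata. Counts are apportioned across strata
by largest remainder so the realized global count is exactly
`round(rate × n)`; a stratum smaller than its quota is capped and the
shortfall logged, never silently redistributed. Within each stratum the
flipped rows are the prefix of one seeded permutation, so for a fixed seed
the flip sets are nested across increasing rates — uniform at every single
rate, and variance-reducing for the sweep. Validation and test labels are
never touched, and the log records realized rate, per-stratum flips, and
class priors before/after.

**Label leakage** appends a binary proxy `leak_s` that agrees with the
sensitive attribute with probability 0.90 (flipping to `1 − s` otherwise),
independently per row, across *all* partitions — systemic leakage. The
column is tagged so the sensitive-exclusion policy deliberately retains it
in the model-facing view. On this generator's cohorts the clinical features
are already highly informative, so the proxy adds little headroom for the
forest (the step-05 analysis shows near-identical accuracy with and without
it); on information-starved real data the same mechanism has far more room
to distort — another reminder of what the synthetic conditions do and do
not show.

Seeds derive as `base + fold + 1000 × repeat` from the base seed 4765416.

## Models

Three delegated learners behind one seeded surface: a decision tree (rpart;
depth 10, minimum leaf 2, Gini), a random forest (ranger; 200 trees, depth
12, minimum split size 4, sqrt features per split, bootstrap on), and a
compact single-hidden-layer perceptron (nnet, logistic activation,
weight-decay regularization) as the neural baseline. Grid search brackets
the final values (e.g. tree depth {5, 10, 15}) over the plan's five
stratified folds; the audited configuration is always a member of its grid.
Model selection uses mean CV validation log-loss by default — selecting on
*training* loss, which the literal protocol suggests, is available as
`selection = "train_loss"` but invites overfitting. The perceptron's
decision threshold is chosen on a validation fold (fold 1 of the plan) to
maximize F1; a model trained on the remaining folds produces the validation
scores, and the final network is refitted on all training rows. Training
never reads held-out rows (asserted by a sentinel-poisoning test), and
retraining under one seed reproduces tree/forest predictions exactly and
perceptron scores to numerical tolerance.

## The experiment harness

`run_grid()` enumerates {models} × {sensitive attributes} × {without/with
mitigation} × {clean/poison/leak}, with five repeats by default. Each repeat
regenerates the cohort and the split under a derived seed (so mean ± SD is
over genuinely fresh draws — fold-wise aggregation over a single split is a
switchable alternative), applies attacks within their scope, fits mitigation
on (possibly tampered) training rows, and always scores the clean test rows.
Cell failures are recorded and the harness continues. Paired t-tests pair
per-repeat values by seed; a zero-variance difference vector is flagged
degenerate with p = 1 rather than an infinite statistic, which would
otherwise manufacture significance from deterministic models. Raw p-values
are reported; an optional Benjamini–Hochberg column is available but off by
default, matching the protocol's unadjusted reporting. Reports render as
CSV tables (rows = metrics, columns = attribute × Without/With), a JSON
summary, and a plain-text delta narrative; every rendered number is
recomputable from the stored per-repeat records.

## Problem sizes and budgets in the shipped tests

The test suite exercises the default 1,082-row cohort where constitution
matters, 10,000-row cohorts for generator convergence, 50,000 rows for the
mitigation law-of-large-numbers check, 100,000 rows for leakage
calibration, 20 seeded runs per planted-bias level for mitigation recovery,
and a 10-seed × 5-rate × 2-model poisoning sweep. These sizes keep each
property statistically meaningful at desk scale; all are ordinary function
arguments, so larger replications are one-line changes.

## Known limitations

* The generator's conditional-independence structure understates
  multicollinearity; the SULOV stage is exercised mainly by planted
  correlated pairs in tests.
* Indiscriminate, group-symmetric label flipping degrades utility
  monotonically but tends to *compress* between-group prediction gaps
  toward base rates rather than widen them (the step-05 sweep shows
  exactly this); widening requires group-asymmetric tampering, which the
  audited attack configuration does not include.
* The mitigation transforms only the two most label-informative features;
  disparities carried by other features are addressed only through the
  label component of the map.
* In-processing (adversarial debiasing) and post-processing threshold
  methods are out of scope, as is reweighing.
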