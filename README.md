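# fairaudit

Fairness and adversarial-robustness auditing of binary clinical classifiers
on tabular cohort data, built around a synthetic Parkinson's-disease (PD)
case/control study.

Clinical ML models are usually judged on accuracy alone, but cohorts like
PD registries are demographically skewed — more male cases, mostly
participants over 60, predominantly White — and their training data can be
tampered with. `fairaudit` is for biostatisticians and ML practitioners who
need to ask, end to end: *is this classifier equitable across race, age and
gender, and what happens to both utility and equity when the training data
is attacked?* Everything runs on a synthetic cohort that reproduces the
published constitution of a real PD study (648 cases / 434 controls, 391
male cases), so the full audit is testable without restricted data.

## What it computes

Per sensitive attribute with privileged group *p* and unprivileged group
*u*, from predictions Ŷ, labels Y and group S:

- **SPD** = P(Ŷ=1 | u) − P(Ŷ=1 | p)  (0 = statistical parity)
- **DI** = P(Ŷ=1 | u) / P(Ŷ=1 | p)  (1 = parity)
- **EOD** = TPR(u) − TPR(p)  (0 = equal opportunity)
- **AAOD** = (|ΔFPR| + |ΔTPR|) / 2, signed by ΔTPR  (0 = equalized odds)

plus the eight per-group rates (TPR, TNR, FPR, FNR, FDR, FOR, PPV, NPV) and
the group loss disparity Δerror = |E[L|S=1] − E[L|S=0]|.

The **optimized pre-processing mitigation** learns a probabilistic map
p(x̂, ŷ | x, y, s) over discretized features and the label by linear
programming: minimize expected distortion subject to a transformed
label-rate gap ≤ ε, a per-(x, y, s) distortion budget, and a
total-variation fidelity budget — then transforms the *training* data only.

The **attacks** are stratified label flipping (y ← 1 − y for 5% of training
labels, uniform within class × group strata, sweep 0–20%) and injection of
a leakage proxy `leak_s` that agrees with a sensitive attribute with
probability 0.90 across all partitions.

## Worked example

```r
library(fairaudit)

ch  <- generate_cohort(cohort_config(bias_strength = -0.30))  # planted gap
pp  <- preprocess_pipeline(ch, seed = 4765416)
y   <- cohort_label(pp$cohort)
fv  <- exclude_sensitive_from_features(pp$cohort)
te  <- pp$plan$test_idx

m   <- train_model(fv, y, pp$plan, model_config("dt", tune = TRUE))
pr  <- predict_model(m, fv[te, ])
g   <- group_vector(pp$cohort, default_sensitive_specs()$gender)[te]
bias_report(pr$pred, y[te], g, attribute = "gender")
#> <bias_report> attribute: gender (n_unpriv 98, n_priv 119)
#>   SPD -0.1571  DI 0.7695  EOD  0.0481  AAOD  0.0429
```

The negative SPD says female participants (the unprivileged bin) receive a
positive PD prediction 15.7 points less often than males; DI 0.77 is the
same disparity as a ratio; EOD near zero says true cases are found at
almost equal rates.

Mitigating the planted disparity before training:

```r
ti  <- pp$plan$train_idx
map <- fit_mitigation(fv[ti, ], y[ti],
                      group_vector(pp$cohort, default_sensitive_specs()$gender)[ti],
                      eps_fairness = 0.05)
map
#> <mitigation_map> 35 conditionings x 18 outcomes; objective 0.2284
#>   implied label rates: unpriv 0.5812, priv 0.6312 (gap -0.0500, eps 0.050)
```

The planted −0.30 label-rate gap is pulled to the −0.05 bound at a minimal
expected distortion of 0.23 (in bin-move/label-flip units).

The numbered drivers under `analysis/` run the full study: `01_simulate.R`
(cohort constitution), `02_preprocess_select.R` (pipeline + feature
selection), `03_baselines.R` (per-attribute bias of DT/RF/MLP),
`04_fairness_audit.R` (the {model} × {attribute} × {without/with
mitigation} grid, 5 repeats, mean ± SD tables and paired t-tests), and
`05_attacks.R` (poisoning sweep and leakage condition). Each prints its
findings and writes tables under `results/`. For example, step 05's sweep
(10 seeds) shows mean DT test accuracy falling 0.887 → 0.791 and RF
0.978 → 0.963 as the poisoning rate rises 0 → 20%.

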