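#!/usr/bin/env Rscript
## Step 3 -- baseline classifiers and their fairness profile.
##
## Trains the decision tree, random forest and perceptron baselines with the
## audited hyperparameters (CV grid search around them), scores the held-out
## rows, and reports overall utility plus the per-attribute bias metrics of
## the audit (SPD, DI, EOD, AAOD), without any mitigation.

suppressPackageStartupMessages(library(fairaudit))
dir.create("results", showWarnings = FALSE)

ch <- generate_cohort(cohort_config(bias_strength = -0.30))
pp <- preprocess_pipeline(ch, seed = 4765416)
y <- cohort_label(pp$cohort)
fv <- exclude_sensitive_from_features(pp$cohort)
te <- pp$plan$test_idx

rows <- list()
for (kind in c("dt", "rf", "mlp")) {
  m <- train_model(fv, y, pp$plan, model_config(kind, tune = TRUE))
  pr <- predict_model(m, fv[te, ])
  for (attr in c("race", "age", "gender")) {
    g <- group_vector(pp$cohort, default_sensitive_specs()[[attr]])[te]
    br <- bias_report(pr$pred, y[te], g, attribute = attr)
    rows[[length(rows) + 1]] <- data.frame(
      model = kind, attribute = attr,
      accuracy = mean(pr$pred == y[te]), auroc = auroc(y[te], pr$score),
      SPD = br$SPD, DI = br$DI, EOD = br$EOD, AAOD = br$AAOD)
  }
}
tab <- do.call(rbind, rows)
tab[, 3:8] <- round(tab[, 3:8], 4)
write.csv(tab, "results/03_baseline_bias.csv", row.names = FALSE)
print(tab, row.names = FALSE)
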