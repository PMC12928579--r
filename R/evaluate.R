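## Experiment harness: {model kinds} x {sensitive attributes} x
## {without/with mitigation} x {clean / poison / leak} with repeated seeded
## runs, mean +- SD aggregation, paired t-tests, and table-shaped reports.
## Each repeat regenerates the cohort and split under a derived seed;
## attacks respect their scope (poison: training labels only; leak: all
## partitions); metrics are always computed on the clean test rows.

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param label binary 0/1 labels.
#' @param score numeric scores.
#' @return AUROC in `[0, 1]`; `NA` if a class is absent.
#' @export
auroc <- function(label, score) {
  pos <- score[label == 1]; neg <- score[label == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Specify an audit experiment
#'
#' @param cohort_config a [cohort_config()]; regenerated per repeat with a
#'   derived seed.
#' @param model_kinds subset of `c("dt", "rf", "mlp")`.
#' @param attributes sensitive attributes to audit (names into `specs`).
#' @param specs named list of [sensitive_spec()]s.
#' @param mitigation conditions to run: any of `FALSE` (without) and `TRUE`
#'   (with optimized pre-processing).
#' @param attack `NULL` (clean), or an [attack_config()]; for poison configs
#'   `poison_rates` may sweep several rates.
#' @param poison_rates numeric vector of poisoning rates (used when `attack`
#'   is a poison config), default the config's single rate.
#' @param repeats number of repeated runs (fresh seed and split each), default 5.
#' @param base_seed base seed; repeat r uses `derive_seed(base_seed, 0, r)`.
#' @param tune whether model training grid-searches (slower) or uses the
#'   final audited hyperparameters directly.
#' @param mitigation_args extra arguments passed to [fit_mitigation()].
#' @return class `experiment_spec`.
#' @export
experiment_spec <- function(cohort_config = fairaudit::cohort_config(),
                            model_kinds = c("dt", "rf"),
                            attributes = c("gender"),
                            specs = default_sensitive_specs(),
                            mitigation = c(FALSE, TRUE),
                            attack = NULL,
                            poison_rates = NULL,
                            repeats = 5L,
                            base_seed = 4765416L,
                            tune = FALSE,
                            mitigation_args = list()) {
  if (!is.null(attack)) stopifnot(inherits(attack, "attack_config"))
  if (is.null(poison_rates) && !is.null(attack) && attack$kind == "poison")
    poison_rates <- attack$poison_rate
  structure(list(cohort_config = cohort_config, model_kinds = model_kinds,
                 attributes = attributes, specs = specs,
                 mitigation = mitigation, attack = attack,
                 poison_rates = poison_rates, repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed), tune = tune,
                 mitigation_args = mitigation_args),
            class = "experiment_spec")
}

run_cell <- function(ch, plan, spec_attr, attr_name, kind, mitigated, attack,
                     rate, seed, tune, mitigation_args) {
  y <- cohort_label(ch)
  g <- group_vector(ch, spec_attr)

  poison_log <- NULL
  if (!is.null(attack) && attack$kind == "poison" && rate > 0) {
    cfg <- attack_config("poison", poison_rate = rate, seed = seed)
    ti <- plan$train_idx
    pz <- poison_labels(y[ti], interaction(y[ti], g[ti]), cfg)
    y_train <- pz$labels
    poison_log <- pz$log
  } else {
    y_train <- y[plan$train_idx]
  }

  ## labels vector used for fitting: training rows possibly tampered,
  ## held-out rows untouched (and never read by train_model)
  y_fit <- y
  y_fit[plan$train_idx] <- y_train

  feats <- exclude_sensitive_from_features(ch)

  mit_log <- NULL
  if (mitigated) {
    ti <- plan$train_idx
    map <- do.call(fit_mitigation, c(
      list(features = feats[ti, , drop = FALSE], labels = y_fit[ti],
           group = g[ti]),
      mitigation_args))
    ap <- apply_mitigation(map, feats[ti, , drop = FALSE], y_fit[ti], g[ti],
                           seed = derive_seed(seed, 7))
    feats[ti, names(ap$features)] <- ap$features
    y_fit[ti] <- ap$labels
    mit_log <- ap$log
  }

  model <- train_model(feats, y_fit, plan,
                       model_config(kind, seed = seed, tune = tune))
  te <- plan$test_idx
  pr <- predict_model(model, feats[te, , drop = FALSE])
  yt <- y[te]; gt <- g[te]

  rep_bias <- bias_report(pr$pred, yt, gt, attribute = attr_name)
  tp <- sum(pr$pred == 1 & yt == 1); fp <- sum(pr$pred == 1 & yt == 0)
  fn <- sum(pr$pred == 0 & yt == 1)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  rates <- rep_bias$rates
  row <- data.frame(
    model = kind, attribute = attr_name, mitigated = mitigated,
    attack = if (is.null(attack)) "clean" else attack$kind,
    poison_rate = rate %||% NA_real_,
    accuracy = mean(pr$pred == yt), precision = prec, recall = rec,
    f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
         else 2 * prec * rec / (prec + rec),
    auroc = auroc(yt, pr$score),
    SPD = rep_bias$SPD, DI = rep_bias$DI, EOD = rep_bias$EOD,
    AAOD = rep_bias$AAOD,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(rates))) {
    suff <- if (rates$group[i] == "privileged") "_priv" else "_unpriv"
    for (m in c("TPR", "TNR", "FPR", "FNR", "FDR", "FOR", "PPV", "NPV"))
      row[[paste0(m, suff)]] <- rates[[m]][i]
  }
  list(row = row, bias = rep_bias, poison_log = poison_log, mit_log = mit_log)
}

#' Run the full audit grid
#'
#' For each repeat: derive a fresh seed, regenerate the cohort, preprocess
#' (fit-on-train statistics), optionally inject the leakage proxy (all
#' partitions), then for every model x attribute x condition cell optionally
#' poison the training labels (per stratum), optionally fit-and-apply
#' mitigation on the training rows, train, and score the clean test rows.
#' Stage errors are recorded per cell and the harness continues.
#'
#' @param spec an [experiment_spec()].
#' @return class `experiment_result`: `records` (one row per repeat x cell),
#'   `aggregates` (mean and SD over repeats per cell), `failures`,
#'   `attack_logs`, `spec`.
#' @export
run_grid <- function(spec) {
  records <- list(); failures <- list(); attack_logs <- list()
  rates <- if (!is.null(spec$attack) && spec$attack$kind == "poison")
    spec$poison_rates else NA_real_
  for (r in seq_len(spec$repeats)) {
    seed_r <- derive_seed(spec$base_seed, 0, r)
    cfg <- spec$cohort_config
    cfg$seed <- seed_r
    ch0 <- generate_cohort(cfg)
    pp <- preprocess_pipeline(ch0, seed = seed_r,
                              specs = spec$specs[spec$attributes])
    ch <- pp$cohort
    if (!is.null(spec$attack) && spec$attack$kind == "leak") {
      ## systemic: injected across train, validation and test rows, after
      ## preprocessing, and retained by the feature-exclusion policy
      lk <- inject_leak_feature(
        ch, group_vector(ch, spec$specs[[spec$attributes[1]]]),
        attack_config("leak", leak_alpha = spec$attack$leak_alpha,
                      seed = seed_r))
      ch <- lk$data
      attack_logs[[length(attack_logs) + 1]] <- lk$log
    }
    for (kind in spec$model_kinds) for (attr in spec$attributes)
      for (mit in spec$mitigation) for (rate in rates) {
        cell <- tryCatch(
          run_cell(ch, pp$plan, spec$specs[[attr]], attr, kind, mit,
                   spec$attack, rate, seed_r, spec$tune,
                   spec$mitigation_args),
          error = function(e) e
        )
        if (inherits(cell, "error")) {
          failures[[length(failures) + 1]] <- list(
            rep = r, model = kind, attribute = attr, mitigated = mit,
            rate = rate, message = conditionMessage(cell))
          next
        }
        cell$row$rep <- r
        cell$row$seed <- seed_r
        records[[length(records) + 1]] <- cell$row
        if (!is.null(cell$poison_log))
          attack_logs[[length(attack_logs) + 1]] <- cell$poison_log
      }
  }
  records <- if (length(records)) do.call(rbind, records) else empty_records()
  structure(list(records = records,
                 aggregates = aggregate_records(records),
                 failures = failures, attack_logs = attack_logs,
                 spec = spec),
            class = "experiment_result")
}

metric_cols <- function() {
  c("accuracy", "precision", "recall", "f1", "auroc",
    "SPD", "DI", "EOD", "AAOD",
    paste0(rep(c("TPR", "TNR", "FPR", "FNR", "FDR", "FOR", "PPV", "NPV"), 2),
           rep(c("_unpriv", "_priv"), each = 8)))
}

empty_records <- function() {
  df <- data.frame(model = character(0), attribute = character(0),
                   mitigated = logical(0), attack = character(0),
                   poison_rate = numeric(0))
  for (m in metric_cols()) df[[m]] <- numeric(0)
  df$rep <- integer(0); df$seed <- integer(0)
  df
}

aggregate_records <- function(records) {
  if (nrow(records) == 0) return(empty_records()[0, ])
  keys <- c("model", "attribute", "mitigated", "attack", "poison_rate")
  ## NA poison_rate (clean/leak conditions) must still form a group
  key <- interaction(records$model, records$attribute, records$mitigated,
                     records$attack, addNA(factor(records$poison_rate)),
                     drop = TRUE)
  out <- list()
  for (grp in split(records, key)) {
    row <- grp[1, keys]
    row$n_repeats <- nrow(grp)
    for (m in metric_cols()) {
      v <- grp[[m]][!is.na(grp[[m]])]
      row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(m, "_sd")]] <- if (length(v) > 1) stats::sd(v)
                                 else if (length(v) == 1) 0 else NA_real_
      row[[paste0(m, "_n_undefined")]] <- sum(is.na(grp[[m]]))
    }
    out[[length(out) + 1]] <- row
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Paired t-tests between two conditions of an experiment
#'
#' Pairs per-repeat metric values by repeat (identical derived seeds across
#' the pair), within each model x attribute cell, and reports the paired t
#' statistic and two-sided p-value per metric, with a significance flag at
#' 0.05. A zero-variance difference vector is reported as degenerate with
#' `p = 1` rather than an infinite statistic.
#'
#' @param result an [run_grid()] result (or its `records`).
#' @param condition column distinguishing the two arms, default `"mitigated"`.
#' @param level_a,level_b the two condition levels (a minus b differences).
#' @param metrics metric columns to test.
#' @return data.frame: model, attribute, metric, mean_diff, statistic, df,
#'   p_value, significant, degenerate.
#' @export
paired_tests <- function(result, condition = "mitigated",
                         level_a = TRUE, level_b = FALSE,
                         metrics = c("accuracy", "f1", "SPD", "EOD")) {
  records <- if (inherits(result, "experiment_result")) result$records else result
  out <- list()
  for (grp in split(records, records[c("model", "attribute")], drop = TRUE)) {
    a <- grp[grp[[condition]] == level_a, ]
    b <- grp[grp[[condition]] == level_b, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    if (nrow(a) != nrow(b)) stopf("unequal repeat counts between arms (%d vs %d)",
                                  nrow(a), nrow(b))
    a <- a[order(a$rep), ]; b <- b[order(b$rep), ]
    if (!all(a$seed == b$seed)) stopf("pairing requires identical seeds across arms")
    if (nrow(a) < 2) stopf("paired test needs at least 2 paired repeats")
    for (m in metrics) {
      d <- a[[m]] - b[[m]]
      d <- d[!is.na(d)]
      degen <- length(d) < 2 || stats::sd(d) == 0
      if (degen) {
        stat <- NA_real_; p <- 1; dfree <- NA_real_
      } else {
        tt <- stats::t.test(a[[m]], b[[m]], paired = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value; dfree <- unname(tt$parameter)
      }
      out[[length(out) + 1]] <- data.frame(
        model = a$model[1], attribute = a$attribute[1], metric = m,
        mean_diff = mean(d), statistic = stat, df = dfree, p_value = p,
        significant = !degen && p < 0.05, degenerate = degen,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render an experiment result to report files
#'
#' Writes, per model x attack condition, a CSV in the published table layout
#' (rows = evaluation metrics, columns = attribute x Without/With
#' mitigation; performance metrics as `mean +- sd` on the percent scale,
#' bias metrics as signed values), a JSON summary of the aggregates, and a
#' plain-text narrative of the mitigation deltas.
#'
#' @param result an [run_grid()] result.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ag <- result$aggregates
  files <- character(0)

  perf <- c(accuracy = "Accuracy", precision = "Precision", recall = "Recall",
            f1 = "F1-score", auroc = "AUROC")
  bias <- c("SPD", "DI", "EOD", "AAOD")
  grp <- paste0(rep(c("TPR", "TNR", "FPR", "FNR", "FDR", "FOR", "PPV", "NPV"), 2),
                rep(c("_unpriv", "_priv"), each = 8))
  row_names <- c(unname(perf), bias, grp)

  combos <- unique(ag[, c("model", "attack", "poison_rate"), drop = FALSE])
  if (nrow(combos) == 0) {
    combos <- data.frame(model = character(0), attack = character(0),
                         poison_rate = numeric(0))
    tab <- data.frame(metric = row_names)
    f <- file.path(dir, "table_empty.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  for (i in seq_len(nrow(combos))) {
    sel <- ag$model == combos$model[i] & ag$attack == combos$attack[i] &
      (is.na(ag$poison_rate) == is.na(combos$poison_rate[i])) &
      (is.na(ag$poison_rate) | ag$poison_rate %in% combos$poison_rate[i])
    sub <- ag[sel, , drop = FALSE]
    tab <- data.frame(metric = row_names, stringsAsFactors = FALSE)
    for (attr in unique(sub$attribute)) for (mit in c(FALSE, TRUE)) {
      cell <- sub[sub$attribute == attr & sub$mitigated == mit, ]
      cn <- paste0(attr, if (mit) "_With" else "_Without")
      if (nrow(cell) == 0) { tab[[cn]] <- NA_character_; next }
      vals <- character(length(row_names))
      for (j in seq_along(perf)) {
        m <- names(perf)[j]
        vals[j] <- sprintf("%.2f ± %.2f", 100 * cell[[paste0(m, "_mean")]],
                           100 * cell[[paste0(m, "_sd")]])
      }
      for (j in seq_along(bias))
        vals[length(perf) + j] <- sprintf("%.4f", cell[[paste0(bias[j], "_mean")]])
      for (j in seq_along(grp))
        vals[length(perf) + length(bias) + j] <-
          sprintf("%.2f", cell[[paste0(grp[j], "_mean")]])
      tab[[cn]] <- vals
    }
    f <- file.path(dir, sprintf("table_%s_%s%s.csv", combos$model[i],
                                combos$attack[i],
                                if (!is.na(combos$poison_rate[i]))
                                  sprintf("_rate%02.0f", 100 * combos$poison_rate[i])
                                else ""))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }

  jf <- file.path(dir, "summary.json")
  jsonlite::write_json(list(aggregates = ag, n_failures = length(result$failures)),
                       jf, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, jf)

  nf <- file.path(dir, "narrative.txt")
  lines <- c("Audit summary: mitigation deltas (With minus Without), by model and attribute.")
  for (g in split(ag, ag[c("model", "attribute", "attack")], drop = TRUE)) {
    w0 <- g[!g$mitigated, ]; w1 <- g[g$mitigated, ]
    if (nrow(w0) == 1 && nrow(w1) == 1) {
      lines <- c(lines, sprintf(
        "%s / %s / %s: accuracy %+0.2f pts, SPD %+0.4f, EOD %+0.4f",
        g$model[1], g$attribute[1], g$attack[1],
        100 * (w1$accuracy_mean - w0$accuracy_mean),
        w1$SPD_mean - w0$SPD_mean, w1$EOD_mean - w0$EOD_mean))
    }
  }
  writeLines(lines, nf)
  files <- c(files, nf)
  invisible(files)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d records, %d failures\n",
              nrow(x$records), length(x$failures)))
  invisible(x)
}
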