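## Thin, seeded orchestration of three delegated learners: a decision tree
## (rpart), a random forest (ranger), and a single-hidden-layer perceptron
## (nnet) as the neural baseline. Hyperparameters default to the audited
## configuration (tree depth 10 / min leaf 2 / Gini; forest of 200 trees,
## depth 12, min split 4, sqrt features per split, bootstrap on); small grid
## search over the stratified CV folds brackets those values.

#' Model configuration
#'
#' @param kind `"dt"` (decision tree), `"rf"` (random forest) or `"mlp"`
#'   (single-hidden-layer perceptron baseline).
#' @param seed integer seed governing fitting randomness.
#' @param tune if `TRUE`, grid-search the kind's small grid over the split
#'   plan's CV folds; if `FALSE`, fit the final configuration directly.
#' @param selection model-selection criterion: `"cv_loss"` (mean validation
#'   log-loss across folds, default) or `"train_loss"` (training log-loss,
#'   the literal lowest-training-loss reading).
#' @param ... kind-specific fields. dt: `max_depth` (10),
#'   `min_samples_leaf` (2), `criterion` ("gini"). rf: `n_trees` (200),
#'   `max_depth` (12), `min_samples_split` (4), `mtry` ("sqrt"),
#'   `bootstrap` (TRUE). mlp: `hidden` (16), `decay` (1e-4), `maxit` (300).
#'   Unknown fields are rejected.
#' @return class `model_config`.
#' @export
model_config <- function(kind = c("dt", "rf", "mlp"), seed = 4765416L,
                         tune = TRUE, selection = c("cv_loss", "train_loss"),
                         ...) {
  kind <- match.arg(kind)
  selection <- match.arg(selection)
  defaults <- switch(kind,
    dt = list(max_depth = 10L, min_samples_leaf = 2L, criterion = "gini"),
    rf = list(n_trees = 200L, max_depth = 12L, min_samples_split = 4L,
              mtry = "sqrt", bootstrap = TRUE),
    mlp = list(hidden = 16L, decay = 1e-4, maxit = 300L)
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stopf("unknown %s config field(s): %s", kind, paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, extra)
  structure(c(list(kind = kind, seed = as.integer(seed), tune = tune,
                   selection = selection), cfg),
            class = "model_config")
}

## small fixed grids bracketing the final audited values (which are members,
## so the reference configuration is always reachable)
model_grid <- function(cfg) {
  if (!cfg$tune) return(list(cfg))
  pts <- switch(cfg$kind,
    dt = lapply(c(5L, 10L, 15L), function(d) utils::modifyList(cfg, list(max_depth = d))),
    rf = lapply(c(8L, 12L, 16L), function(d) utils::modifyList(cfg, list(max_depth = d))),
    mlp = {
      out <- list()
      for (h in c(8L, 16L)) for (dc in c(1e-3, 1e-4))
        out[[length(out) + 1]] <- utils::modifyList(cfg, list(hidden = h, decay = dc))
      out
    }
  )
  lapply(pts, function(p) { class(p) <- "model_config"; p })
}

logloss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

fit_one <- function(cfg, X, y, seed) {
  X <- as.data.frame(X)
  switch(cfg$kind,
    dt = {
      df <- cbind(X, .y = factor(y, levels = c(0, 1)))
      with_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = if (cfg$criterion == "gini") "gini" else "information"),
        control = rpart::rpart.control(maxdepth = cfg$max_depth,
                                       minbucket = cfg$min_samples_leaf,
                                       minsplit = 2 * cfg$min_samples_leaf,
                                       cp = 0, xval = 0)
      ))
    },
    rf = {
      df <- cbind(X, .y = factor(y, levels = c(0, 1)))
      mtry <- if (identical(cfg$mtry, "sqrt")) max(1L, floor(sqrt(ncol(X)))) else cfg$mtry
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = cfg$n_trees, max.depth = cfg$max_depth,
        min.node.size = cfg$min_samples_split, mtry = mtry,
        replace = cfg$bootstrap, probability = TRUE,
        seed = seed, num.threads = 1
      )
    },
    mlp = with_seed(seed, nnet::nnet(
      as.matrix(X), y, size = cfg$hidden, decay = cfg$decay,
      maxit = cfg$maxit, entropy = TRUE, trace = FALSE, MaxNWts = 10000
    ))
  )
}

score_one <- function(kind, fit, X) {
  X <- as.data.frame(X)
  switch(kind,
    dt = unname(stats::predict(fit, X, type = "prob")[, "1"]),
    rf = unname(stats::predict(fit, data = X, num.threads = 1)$predictions[, "1"]),
    mlp = as.numeric(stats::predict(fit, as.matrix(X)))
  )
}

#' Train a classifier under a split plan
#'
#' Grid-searches the kind's small hyperparameter grid over the plan's
#' stratified CV folds (training rows only -- test rows are never touched),
#' selects by the configured criterion, and refits the winner on the full
#' training portion. For the neural baseline the decision threshold is
#' selected on the validation fold (fold 1 of the plan) to maximize F1;
#' tree models use the 0.5 threshold.
#'
#' @param features data.frame of model-facing features for *all* rows (the
#'   plan indexes into it); must contain no missing values.
#' @param labels binary 0/1 labels for all rows.
#' @param plan a [split_cohort()] plan.
#' @param cfg a [model_config()].
#' @return class `trained_model`: fitted learner, config echo, chosen grid
#'   point, threshold, training log.
#' @export
train_model <- function(features, labels, plan, cfg = model_config("rf")) {
  features <- as.data.frame(features)
  stopifnot(!anyNA(features))
  y <- as.integer(labels)
  ti <- plan$train_idx
  Xtr <- features[ti, , drop = FALSE]
  ytr <- y[ti]
  if (length(unique(ytr)) < 2) stopf("degenerate single-class training set")

  grid <- model_grid(cfg)
  cv_records <- list()
  losses <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    g <- grid[[gi]]
    if (cfg$selection == "train_loss" || length(grid) == 1) {
      fit <- fit_one(g, Xtr, ytr, seed = g$seed)
      losses[gi] <- logloss(ytr, score_one(g$kind, fit, Xtr))
    } else {
      fl <- numeric(plan$n_folds)
      for (f in seq_len(plan$n_folds)) {
        tr <- plan$folds != f
        if (length(unique(ytr[tr])) < 2) stopf("degenerate single-class training fold")
        fit <- fit_one(g, Xtr[tr, , drop = FALSE], ytr[tr],
                       seed = derive_seed(g$seed, f))
        fl[f] <- logloss(ytr[!tr], score_one(g$kind, fit, Xtr[!tr, , drop = FALSE]))
      }
      losses[gi] <- mean(fl)
    }
    cv_records[[gi]] <- list(grid_point = gi, loss = losses[gi])
  }
  best <- grid[[which.min(losses)]]

  final <- fit_one(best, Xtr, ytr, seed = best$seed)

  threshold <- 0.5
  if (cfg$kind == "mlp") {
    val <- plan$folds == 1
    vfit <- fit_one(best, Xtr[!val, , drop = FALSE], ytr[!val],
                    seed = derive_seed(best$seed, 99))
    vs <- score_one("mlp", vfit, Xtr[val, , drop = FALSE])
    threshold <- best_f1_threshold(ytr[val], vs)
  }

  structure(list(
    kind = cfg$kind, fit = final, config = cfg, chosen = best,
    threshold = threshold, feature_names = names(features),
    log = list(grid = cv_records, chosen_index = which.min(losses),
               n_train = length(ti), selection = cfg$selection)
  ), class = "trained_model")
}

best_f1_threshold <- function(y, scores, grid = seq(0.05, 0.95, by = 0.01)) {
  f1 <- vapply(grid, function(t) {
    p <- as.integer(scores >= t)
    tp <- sum(p == 1 & y == 1)
    if (tp == 0) return(0)
    prec <- tp / sum(p == 1); rec <- tp / sum(y == 1)
    2 * prec * rec / (prec + rec)
  }, 0)
  grid[which.max(f1)]
}

#' Predict with a trained model
#'
#' The feature schema must match training exactly (same names, same order);
#' mismatches error listing the missing/extra columns.
#'
#' @param model a [train_model()] result.
#' @param features data.frame of rows to score.
#' @return list: `pred` (binary, thresholded), `score` (in `[0, 1]`).
#' @export
predict_model <- function(model, features) {
  features <- as.data.frame(features)
  if (!identical(names(features), model$feature_names)) {
    missing <- setdiff(model$feature_names, names(features))
    extra <- setdiff(names(features), model$feature_names)
    stopf("feature schema mismatch: missing [%s], extra [%s] (order must match)",
          paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  s <- score_one(model$kind, model$fit, features)
  list(pred = as.integer(s >= model$threshold), score = s)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> kind %s, %d training rows, threshold %.2f\n",
              x$kind, x$log$n_train, x$threshold))
  invisible(x)
}
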