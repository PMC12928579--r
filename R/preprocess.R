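## Deterministic data preparation: cleaning, missingness filtering,
## imputation, min-max normalization, sensitive-attribute binarization,
## stratified splitting. Fitted statistics (medians, modes, min/max) use
## training rows only unless fit_scope = "all".

MISSING_TOKENS <- c("", "NA", "N/A", "n/a", "na", "NaN", "nan", "NULL",
                    "null", "?", ".")

#' Clean a cohort: deduplicate rows and repair text-coded numbers
#'
#' Exact duplicate rows are removed (first occurrence kept, order preserved).
#' Character columns whose non-missing values all parse as numbers are coerced
#' to numeric; recognized missing tokens (`"N/A"`, `"?"`, ...) become `NA`.
#' Cleaning always succeeds; change counts are appended to the audit log.
#'
#' @param ch a cohort.
#' @return the cleaned cohort.
#' @export
clean <- function(ch) {
  df <- as.data.frame(ch)
  dup <- duplicated(df)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL

  coerced_cols <- character(0); na_cells <- 0L
  for (nm in names(df)) {
    x <- df[[nm]]
    if (!is.character(x)) next
    x[trimws(x) %in% MISSING_TOKENS] <- NA_character_
    obs <- x[!is.na(x)]
    num <- suppressWarnings(as.numeric(obs))
    if (length(obs) > 0 && !anyNA(num)) {
      na_cells <- na_cells + sum(is.na(x) & !is.na(df[[nm]]))
      df[[nm]] <- suppressWarnings(as.numeric(x))
      coerced_cols <- c(coerced_cols, nm)
    } else if (anyNA(x) && !identical(x, df[[nm]])) {
      na_cells <- na_cells + sum(is.na(x) & !is.na(df[[nm]]))
      df[[nm]] <- x
    }
  }
  out <- rebuild(ch, df)
  append_log(out, "clean", list(duplicates_removed = sum(dup),
                                columns_coerced = coerced_cols,
                                cells_set_missing = na_cells))
}

#' Drop clinical features with excessive missingness
#'
#' Removes every clinical feature whose missing fraction is strictly greater
#' than `threshold` (default 0.30, i.e. "more than 30% missing"); a feature at
#' exactly the threshold is retained. Sensitive, label and leak columns are
#' never removed.
#'
#' @param ch a cohort.
#' @param threshold missingness proportion in `[0, 1]`.
#' @return the filtered cohort; removed names go to the audit log.
#' @export
drop_high_missingness <- function(ch, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold <= 1)
  clin <- cols_by_role(ch, "clinical")
  frac <- vapply(clin, function(nm) mean(is.na(ch[[nm]])), 0)
  drop <- clin[frac > threshold]
  if (length(drop) == length(clin))
    stopf("all clinical features exceed %.0f%% missingness; pipeline cannot proceed",
          100 * threshold)
  df <- as.data.frame(ch)[, setdiff(names(ch), drop), drop = FALSE]
  out <- rebuild(ch, df)
  append_log(out, "drop_high_missingness",
             list(threshold = threshold, removed = drop,
                  missing_fraction = as.list(frac)))
}

stat_mode <- function(x) {
  ## most frequent value; ties broken by smallest value (determinism)
  tb <- table(x)
  winners <- names(tb)[tb == max(tb)]
  w <- sort(winners)[1]
  if (is.numeric(x)) as.numeric(w) else w
}

#' Impute missing cells: median for numeric, mode for categorical
#'
#' Statistics are fitted on `train_idx` rows only (default: all rows) and
#' applied everywhere, so held-out rows never inform the imputation. Mode ties
#' break to the smallest value. A feature with zero observed fitting values is
#' an error naming the feature.
#'
#' @param ch a cohort.
#' @param train_idx integer row indices to fit on; `NULL` fits on all rows.
#' @return the imputed cohort (no missing cells remain in imputed columns).
#' @export
impute <- function(ch, train_idx = NULL) {
  df <- as.data.frame(ch)
  idx <- train_idx %||% seq_len(nrow(df))
  cols <- cols_by_role(ch, c("clinical", "sensitive", "leak"))
  filled <- list()
  for (nm in cols) {
    x <- df[[nm]]
    if (!anyNA(x)) next
    obs <- x[idx][!is.na(x[idx])]
    if (length(obs) == 0)
      stopf("feature '%s' has no observed values in the fitting rows", nm)
    val <- if (is.numeric(x)) stats::median(obs) else stat_mode(obs)
    filled[[nm]] <- list(value = val, n_filled = sum(is.na(x)))
    x[is.na(x)] <- val
    df[[nm]] <- x
  }
  out <- rebuild(ch, df)
  append_log(out, "impute", list(fit_rows = length(idx), filled = filled))
}

#' Min-max normalize clinical features onto `[c, d]`
#'
#' Implements `y' = (y - y_min) / (y_max - y_min) * (d - c) + c` per feature,
#' with the default target interval `[0, 1]`. `y_min`/`y_max` are fitted on
#' `train_idx` rows only (default: all rows) and applied everywhere;
#' out-of-range values in non-fitting rows are clipped to `[c, d]` (counts
#' logged). A constant feature maps to `c`.
#'
#' @param ch a cohort (imputation complete for the normalized columns).
#' @param params `"fit"` to fit fresh parameters, or a `normalization_params`
#'   object from a previous fit to re-apply.
#' @param train_idx rows used for fitting; `NULL` = all rows.
#' @param range target interval `c(c, d)`, `d > c`.
#' @return list with elements `cohort` and `params` (class
#'   `normalization_params`: per-feature `y_min`, `y_max`, plus `c`, `d`).
#' @export
minmax_normalize <- function(ch, params = "fit", train_idx = NULL,
                             range = c(0, 1)) {
  cc <- range[1]; dd <- range[2]
  stopifnot(dd > cc)
  cols <- cols_by_role(ch, "clinical")
  df <- as.data.frame(ch)
  if (identical(params, "fit")) {
    idx <- train_idx %||% seq_len(nrow(df))
    ymin <- vapply(cols, function(nm) min(df[[nm]][idx]), 0)
    ymax <- vapply(cols, function(nm) max(df[[nm]][idx]), 0)
    params <- structure(list(y_min = ymin, y_max = ymax, c = cc, d = dd),
                        class = "normalization_params")
  } else {
    stopifnot(inherits(params, "normalization_params"))
    cc <- params$c; dd <- params$d
  }
  clipped <- 0L; constant <- character(0)
  for (nm in cols) {
    y <- df[[nm]]
    ymin <- params$y_min[[nm]]; ymax <- params$y_max[[nm]]
    if (is.null(ymin)) next
    if (ymax > ymin) {
      yp <- (y - ymin) / (ymax - ymin) * (dd - cc) + cc
    } else {
      yp <- rep(cc, length(y))  # constant feature: printed formula undefined
      constant <- c(constant, nm)
    }
    out_of <- sum(yp < cc | yp > dd, na.rm = TRUE)
    clipped <- clipped + out_of
    df[[nm]] <- pmin(pmax(yp, cc), dd)
  }
  out <- rebuild(ch, df)
  out <- append_log(out, "minmax_normalize",
                    list(range = c(cc, dd), clipped_cells = clipped,
                         constant_features = constant))
  list(cohort = out, params = params)
}

#' Add binary privileged-group columns for the sensitive attributes
#'
#' For every spec, appends a column `<attribute>_priv` (1 = privileged bin)
#' with role `sensitive_bin`. Raw sensitive columns are retained for audit and
#' stay excluded from the model-facing feature view.
#'
#' @param ch a cohort.
#' @param specs list of [sensitive_spec()]s; default [default_sensitive_specs()].
#' @return the augmented cohort.
#' @export
binarize_sensitive <- function(ch, specs = default_sensitive_specs()) {
  df <- as.data.frame(ch)
  rl <- roles(ch)
  for (spec in specs) {
    nm <- paste0(spec$attribute, "_priv")
    df[[nm]] <- group_vector(ch, spec)
    rl[nm] <- "sensitive_bin"
  }
  out <- rebuild(ch, df, roles_new = rl)
  append_log(out, "binarize_sensitive",
             list(columns = paste0(vapply(specs, `[[`, "", "attribute"), "_priv")))
}

#' Stratified 80/20 split with 5 stratified CV folds
#'
#' Hold-out rows are drawn per label stratum (test fraction within each class
#' equals `test_frac` up to rounding); the remaining training rows receive
#' fold assignments that preserve class proportions within +-1 row per fold.
#'
#' @param ch a cohort (labels present).
#' @param seed integer seed; the plan is reproducible under it.
#' @param test_frac held-out fraction, default 0.20.
#' @param n_folds number of CV folds within the training rows, default 5.
#' @return a `split_plan`: `train_idx`, `test_idx`, `folds` (integer fold id
#'   per training row, parallel to `train_idx`), `seed`.
#' @export
split_cohort <- function(ch, seed = 1L, test_frac = 0.20, n_folds = 5L) {
  y <- cohort_label(ch)
  with_seed(seed, {
    test_idx <- integer(0)
    for (cls in sort(unique(y))) {
      rows <- which(y == cls)
      k <- as.integer(round(test_frac * length(rows)))
      test_idx <- c(test_idx, sample(rows, k))
    }
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_along(y), test_idx)
    for (cls in unique(y)) {
      if (sum(y[train_idx] == cls) < n_folds)
        stopf("class %s has fewer than %d training members", cls, n_folds)
    }
    folds <- integer(length(train_idx))
    for (cls in sort(unique(y))) {
      pos <- which(y[train_idx] == cls)
      folds[sample(pos)] <- rep_len(seq_len(n_folds), length(pos))
    }
    structure(list(train_idx = train_idx, test_idx = test_idx, folds = folds,
                   n_folds = as.integer(n_folds), test_frac = test_frac,
                   seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Full deterministic preprocessing pipeline
#'
#' Fixed stage order: clean, missingness filter, split-plan creation,
#' imputation, min-max normalization, sensitive binarization. The split plan
#' is drawn immediately after filtering so that imputation and normalization
#' statistics can be fitted on training rows only (`fit_scope = "train"`,
#' the default leakage-safe reading); `fit_scope = "all"` reproduces the
#' laxer reading in which statistics see every row.
#'
#' @param ch a raw cohort.
#' @param seed seed for the split plan.
#' @param specs sensitive specs for binarization.
#' @param miss_threshold missingness filter threshold.
#' @param fit_scope `"train"` or `"all"`.
#' @return list: `cohort` (fully preprocessed), `plan`, `norm_params`.
#' @export
preprocess_pipeline <- function(ch, seed = 1L,
                                specs = default_sensitive_specs(),
                                miss_threshold = 0.30,
                                fit_scope = c("train", "all")) {
  fit_scope <- match.arg(fit_scope)
  ch <- clean(ch)
  ch <- drop_high_missingness(ch, miss_threshold)
  plan <- split_cohort(ch, seed = seed)
  idx <- if (fit_scope == "train") plan$train_idx else NULL
  ch <- impute(ch, train_idx = idx)
  nm <- minmax_normalize(ch, train_idx = idx)
  ch <- binarize_sensitive(nm$cohort, specs)
  list(cohort = ch, plan = plan, norm_params = nm$params)
}
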