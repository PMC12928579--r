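## Feature selection: SULOV-style removal of correlated, lower-relevance
## features, then recursive importance ranking with a gradient-boosted
## ensemble (delegated to xgboost).

#' Plug-in mutual information between a feature and a binary label
#'
#' Numeric features are discretized into up to `bins` quantile bins first.
#' Used as the single-feature relevance score for SULOV tie-breaking.
#'
#' @param x feature vector (numeric or categorical).
#' @param y binary label vector.
#' @param bins number of quantile bins for numeric `x`.
#' @return mutual information in nats, `>= 0`.
#' @export
mutual_information <- function(x, y, bins = 8L) {
  if (is.numeric(x) && length(unique(x)) > bins) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                 na.rm = TRUE))
    x <- cut(x, breaks = br, include.lowest = TRUE)
  }
  tb <- table(x, y)
  p <- tb / sum(tb)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  max(mi, 0)
}

#' SULOV filter: drop the lower-relevance member of correlated pairs
#'
#' Among every feature pair with absolute Pearson correlation strictly above
#' `corr_threshold`, the member with lower mutual information with the label
#' is removed (ties break to keep the earlier column). Pairs are processed
#' greedily, highest correlation first; a pair is skipped when either member
#' was already removed.
#'
#' @param features data.frame / matrix of features (no missing values).
#' @param labels binary label vector.
#' @param corr_threshold correlation ceiling, default 0.70.
#' @return class `selection_result`: `retained`, `removed`,
#'   `removed_pairs` (data.frame: kept, removed, correlation), `relevance`.
#' @export
sulov_filter <- function(features, labels, corr_threshold = 0.70) {
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 2, !anyNA(features))
  nm <- names(features)
  rel <- vapply(nm, function(n) mutual_information(features[[n]], labels), 0)
  cm <- suppressWarnings(stats::cor(as.matrix(features)))
  cm[is.na(cm)] <- 0
  pairs <- which(upper.tri(cm) & abs(cm) > corr_threshold, arr.ind = TRUE)
  alive <- stats::setNames(rep(TRUE, length(nm)), nm)
  removed_pairs <- data.frame(kept = character(0), removed = character(0),
                              correlation = numeric(0))
  if (nrow(pairs) > 0) {
    ord <- order(abs(cm[pairs]), decreasing = TRUE)
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!alive[nm[i]] || !alive[nm[j]]) next
      ## drop lower relevance; tie -> drop the later column
      drop_j <- rel[nm[j]] <= rel[nm[i]]
      dropped <- if (drop_j) nm[j] else nm[i]
      kept <- if (drop_j) nm[i] else nm[j]
      alive[dropped] <- FALSE
      removed_pairs <- rbind(removed_pairs, data.frame(
        kept = kept, removed = dropped, correlation = cm[i, j]))
    }
  }
  structure(list(
    retained = nm[alive[nm]],
    removed = nm[!alive[nm]],
    removed_pairs = removed_pairs,
    relevance = rel,
    corr_threshold = corr_threshold
  ), class = "selection_result")
}

fit_booster <- function(X, y, seed, nrounds = 50, max_depth = 4, eta = 0.3) {
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1),
    data = dm, nrounds = nrounds, verbose = 0
  ))
}

booster_gain <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  g <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0) g[imp$Feature] <- imp$Gain
  g
}

#' Recursive boosted-importance feature selection
#'
#' After the SULOV filter, repeatedly fits a gradient-boosted tree ensemble
#' on the surviving features, ranks them by gain importance, and keeps the
#' top `keep_frac`; rounds stop early once the set stabilizes. Because each
#' round keeps a subset of the previous one, the final set equals the set of
#' features retained in every round.
#'
#' @param features data.frame of features (no missing values, training rows
#'   only -- never test rows, never sensitive columns).
#' @param labels binary label vector.
#' @param rounds maximum selection rounds, default 3.
#' @param keep_frac fraction of features kept per round, default 0.75.
#' @param corr_threshold passed to [sulov_filter()].
#' @param seed integer seed; the result is deterministic under it.
#' @return class `selection_result` with `retained`, per-round `history`
#'   (feature, gain, round), `removed_pairs` from the SULOV stage, `rounds`.
#' @export
recursive_importance_select <- function(features, labels, rounds = 3L,
                                        keep_frac = 0.75,
                                        corr_threshold = 0.70, seed = 1L) {
  stopifnot(keep_frac > 0, keep_frac <= 1)
  features <- as.data.frame(features)
  sul <- sulov_filter(features, labels, corr_threshold)
  current <- sul$retained
  history <- data.frame(feature = character(0), gain = numeric(0),
                        round = integer(0))
  executed <- 0L
  for (r in seq_len(rounds)) {
    if (keep_frac == 1) break  # identity selection, no refit needed
    model <- fit_booster(features[current], labels, seed = derive_seed(seed, r))
    gain <- booster_gain(model, current)
    history <- rbind(history, data.frame(feature = current,
                                         gain = as.numeric(gain[current]),
                                         round = r))
    keep_n <- max(1L, as.integer(ceiling(keep_frac * length(current))))
    ranked <- names(sort(gain, decreasing = TRUE))
    new_set <- current[current %in% ranked[seq_len(keep_n)]]
    executed <- r
    if (setequal(new_set, current)) { current <- new_set; break }
    current <- new_set
  }
  structure(list(
    retained = current,
    removed = setdiff(names(features), current),
    removed_pairs = sul$removed_pairs,
    relevance = sul$relevance,
    history = history,
    rounds = executed,
    keep_frac = keep_frac,
    corr_threshold = corr_threshold,
    seed = as.integer(seed)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d retained, %d removed (%d correlated pairs)\n",
              length(x$retained), length(x$removed),
              nrow(x$removed_pairs %||% data.frame())))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param x a `selection_result`.
#' @param path output path.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
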