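## Independent brute-force oracles, deliberately naive: plain loops and
## recounts, sharing no code with the package implementations they check.

oracle_confusion <- function(pred, label, group, g) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (group[i] != g) next
    if (pred[i] == 1 && label[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && label[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && label[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && label[i] == 1) fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_rate <- function(num, den) if (den == 0) NA_real_ else unname(num / den)

oracle_rates <- function(cf) {
  c(TPR = oracle_rate(cf["TP"], cf["TP"] + cf["FN"]),
    TNR = oracle_rate(cf["TN"], cf["TN"] + cf["FP"]),
    FPR = oracle_rate(cf["FP"], cf["FP"] + cf["TN"]),
    FNR = oracle_rate(cf["FN"], cf["FN"] + cf["TP"]),
    FDR = oracle_rate(cf["FP"], cf["FP"] + cf["TP"]),
    FOR = oracle_rate(cf["FN"], cf["FN"] + cf["TN"]),
    PPV = oracle_rate(cf["TP"], cf["TP"] + cf["FP"]),
    NPV = oracle_rate(cf["TN"], cf["TN"] + cf["FN"]))
}

oracle_pos_rate <- function(pred, group, g) {
  k <- 0; n <- 0
  for (i in seq_along(pred)) if (group[i] == g) { n <- n + 1; k <- k + (pred[i] == 1) }
  if (n == 0) NA_real_ else k / n
}

oracle_spd <- function(pred, group)
  oracle_pos_rate(pred, group, 0) - oracle_pos_rate(pred, group, 1)

oracle_di <- function(pred, group) {
  pp <- oracle_pos_rate(pred, group, 1)
  pu <- oracle_pos_rate(pred, group, 0)
  if (is.na(pp) || is.na(pu) || pp == 0) NA_real_ else pu / pp
}

oracle_tpr <- function(pred, label, group, g) {
  cf <- oracle_confusion(pred, label, group, g)
  oracle_rate(cf["TP"], cf["TP"] + cf["FN"])
}

oracle_fpr <- function(pred, label, group, g) {
  cf <- oracle_confusion(pred, label, group, g)
  oracle_rate(cf["FP"], cf["FP"] + cf["TN"])
}

oracle_eod <- function(pred, label, group)
  unname(oracle_tpr(pred, label, group, 0) - oracle_tpr(pred, label, group, 1))

oracle_aaod_mag <- function(pred, label, group) {
  dt <- oracle_tpr(pred, label, group, 0) - oracle_tpr(pred, label, group, 1)
  df <- oracle_fpr(pred, label, group, 0) - oracle_fpr(pred, label, group, 1)
  unname((abs(df) + abs(dt)) / 2)
}

random_triple <- function(n = 40) {
  list(pred = sample(0:1, n, replace = TRUE),
       label = sample(0:1, n, replace = TRUE),
       group = sample(0:1, n, replace = TRUE))
}

## plain data.frame view of a cohort, stripped of bookkeeping attributes
plain_df <- function(ch) {
  d <- as.data.frame(ch)
  attr(d, "audit_log") <- NULL
  attr(d, "roles") <- NULL
  class(d) <- "data.frame"
  d
}

## build a minimal cohort from a clinical data.frame + label (+ optional
## sensitive columns), for preprocessing tests
make_cohort <- function(clinical, label, sensitive = NULL) {
  df <- as.data.frame(clinical)
  if (!is.null(sensitive)) df <- cbind(df, as.data.frame(sensitive))
  df$label <- label
  rl <- c(setNames(rep("clinical", ncol(clinical)), colnames(clinical)),
          if (!is.null(sensitive))
            setNames(rep("sensitive", ncol(sensitive)), colnames(sensitive)),
          label = "label")
  cohort(df, rl)
}

## hand-built single-feature scheme with two bins (values near 0 and near 1)
toy_scheme <- function() {
  structure(list(
    map_features = "f",
    breaks = list(f = c(-0.5, 0.5, 1.5)),
    representatives = list(f = c(0, 1)),
    n_bins = c(f = 2L),
    cell_grid = matrix(1:2, ncol = 1, dimnames = list(NULL, "f"))
  ), class = "discretization_scheme")
}

## the 2-cell x 2-label x 2-group toy instance: group 0 label rate 0.5,
## group 1 label rate 0.2 (gap 0.3), conditioning weights chosen so every
## achievable group rate lies on a 0.0125 lattice under step-0.25 simplex
## enumeration
toy_data <- function() {
  blocks <- rbind(
    expand.grid(cell = 1, y = 1, s = 0)[rep(1, 40), ],
    expand.grid(cell = 2, y = 1, s = 0)[rep(1, 10), ],
    expand.grid(cell = 1, y = 0, s = 0)[rep(1, 25), ],
    expand.grid(cell = 2, y = 0, s = 0)[rep(1, 25), ],
    expand.grid(cell = 1, y = 1, s = 1)[rep(1, 10), ],
    expand.grid(cell = 2, y = 1, s = 1)[rep(1, 10), ],
    expand.grid(cell = 1, y = 0, s = 1)[rep(1, 40), ],
    expand.grid(cell = 2, y = 0, s = 1)[rep(1, 40), ]
  )
  data.frame(f = blocks$cell - 1, y = blocks$y, s = blocks$s)
}

## Exhaustive lattice oracle for the 2-cell x 2-label x 2-group mitigation
## toy. Enumerates, per group, every assignment of its 4 conditional
## distributions over the 4 outcomes on a step-0.25 simplex lattice
## (35^4 = 1.5e6 product combinations per group), keeps the distortion-
## feasible ones, reduces to the cheapest candidate per achievable group
## rate (rates land exactly on a finite lattice when the conditioning
## weights are uniform), and combines the two groups over fairness-
## compatible rate pairs. The fidelity budget must be non-binding (checked
## elsewhere); use toys with fid_budget = 1.
toy_grid_oracle <- function(cond, P_cond, D, eps, dist_budget, step = 0.25) {
  stopifnot(nrow(cond) == 8)          # 2 cells x 2 labels x 2 groups
  outcomes <- expand.grid(cell = 1:2, yhat = 0:1)
  pos_cols <- which(outcomes$yhat == 1)
  k <- round(1 / step)
  comps <- expand.grid(a = 0:k, b = 0:k, c = 0:k)
  comps$d <- k - comps$a - comps$b - comps$c
  comps <- as.matrix(comps[comps$d >= 0, c("a", "b", "c", "d")]) / k

  best_by_rate <- list()
  for (g in 0:1) {
    ks <- which(cond$s == g)
    stopifnot(length(ks) == 4)
    Pg <- P_cond[ks] / sum(P_cond[ks])
    n <- nrow(comps)
    idx <- as.matrix(expand.grid(i1 = 1:n, i2 = 1:n, i3 = 1:n, i4 = 1:n))
    obj <- rep(0, nrow(idx)); rate <- rep(0, nrow(idx))
    ok <- rep(TRUE, nrow(idx))
    for (j in 1:4) {
      pj <- comps[idx[, j], , drop = FALSE]
      dj <- as.vector(pj %*% D[ks[j], ])
      ok <- ok & (dj <= dist_budget + 1e-12)
      obj <- obj + P_cond[ks[j]] * dj
      rate <- rate + Pg[j] * rowSums(pj[, pos_cols, drop = FALSE])
    }
    obj <- obj[ok]; rate <- round(rate[ok], 9)
    best_by_rate[[g + 1]] <- tapply(obj, rate, min)
  }
  r0 <- as.numeric(names(best_by_rate[[1]]))
  r1 <- as.numeric(names(best_by_rate[[2]]))
  best <- Inf
  for (i in seq_along(r0)) {
    compat <- abs(r0[i] - r1) <= eps + 1e-12
    if (any(compat))
      best <- min(best, best_by_rate[[1]][i] + min(best_by_rate[[2]][compat]))
  }
  unname(best)
}
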