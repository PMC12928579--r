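## Optimized pre-processing fairness mitigation: learn a probabilistic map
## p(x_hat, y_hat | x, y, s) over discretized feature cells and the binary
## label that minimizes expected distortion subject to (a) a bound on the
## transformed group label-rate gap, (b) a per-(x, y, s) distortion budget,
## and (c) a total-variation fidelity budget on the transformed (x, y)
## marginal. The optimization is a linear program; it is solved as a
## vanishing-ridge quadratic program (min c'x + lambda/2 ||x||^2 with
## lambda = 1e-8) through quadprog's dual active-set method, which is
## numerically robust on the LP's highly degenerate constraint structure
## and returns the least-norm optimum of the LP face.

#' Quantile discretization scheme for the mitigation map
#'
#' Bins each mapped feature into (up to) `bins` quantile bins; every row maps
#' to exactly one cell of the resulting grid, and each bin carries the median
#' of its observed values as representative.
#'
#' @param features data.frame of numeric features (fitting rows).
#' @param map_features names of the features entering the map; default: the
#'   2 features most informative about `labels` (mutual information).
#' @param labels binary labels (only used to pick default `map_features`).
#' @param bins quantile bins per feature, default 3.
#' @return class `discretization_scheme`: per-feature `breaks`,
#'   `representatives`, `n_bins`, and the flattened `cells` grid.
#' @export
discretization_scheme <- function(features, map_features = NULL, labels = NULL,
                                  bins = 3L) {
  features <- as.data.frame(features)
  if (is.null(map_features)) {
    stopifnot(!is.null(labels))
    mi <- vapply(names(features),
                 function(n) mutual_information(features[[n]], labels), 0)
    map_features <- names(sort(mi, decreasing = TRUE))[seq_len(min(2L, ncol(features)))]
  }
  stopifnot(all(map_features %in% names(features)))
  brk <- list(); rep_val <- list(); nb <- integer(0)
  for (nm in map_features) {
    x <- features[[nm]]
    b <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(b) < 2) b <- c(b[1] - 0.5, b[1] + 0.5)  # constant feature
    bi <- bin_index(x, b)
    reps <- vapply(seq_len(length(b) - 1), function(k) {
      v <- x[bi == k]
      if (length(v)) stats::median(v) else (b[k] + b[k + 1]) / 2
    }, 0)
    brk[[nm]] <- b; rep_val[[nm]] <- reps; nb[nm] <- length(b) - 1
  }
  grid <- as.matrix(do.call(expand.grid, lapply(nb, seq_len)))
  colnames(grid) <- map_features
  structure(list(map_features = map_features, breaks = brk,
                 representatives = rep_val, n_bins = nb, cell_grid = grid),
            class = "discretization_scheme")
}

## bin index with clamping: values outside the fitted range go to the
## nearest (first/last) bin
bin_index <- function(x, breaks) {
  i <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(breaks) - 1L)
}

## map rows to flat cell ids (1..prod(n_bins)); counts clamped rows
assign_cells <- function(scheme, features) {
  nb <- scheme$n_bins
  mult <- cumprod(c(1, utils::head(nb, -1)))
  cell <- rep(1L, nrow(features))
  clamped <- 0L
  for (j in seq_along(scheme$map_features)) {
    nm <- scheme$map_features[j]
    x <- features[[nm]]
    b <- scheme$breaks[[nm]]
    clamped <- clamped + sum(x < b[1] | x > b[length(b)])
    cell <- cell + (bin_index(x, b) - 1L) * mult[j]
  }
  list(cell = as.integer(cell), clamped = clamped)
}

## per-cell Hamming distance between two flat cell ids (number of differing
## bin coordinates)
cell_hamming <- function(scheme) {
  g <- scheme$cell_grid
  C <- nrow(g)
  H <- matrix(0L, C, C)
  for (j in seq_len(ncol(g))) H <- H + outer(g[, j], g[, j], "!=")
  H
}

#' Fit the optimized pre-processing mitigation map
#'
#' Solves the linear program: minimize expected distortion
#' `E[Delta(x, y; x_hat, y_hat)]` over conditional distributions
#' `p(x_hat, y_hat | x, y, s)` subject to
#' group fairness `|P(y_hat = 1 | s = 0) - P(y_hat = 1 | s = 1)| <= eps_fairness`,
#' per-conditioning distortion `E[Delta | x, y, s] <= distortion_budget`, and
#' fidelity `TV(transformed (x, y) marginal, original) <= fidelity_budget`.
#' Distortion is the per-feature Hamming distance on discrete cells plus
#' `label_flip_weight` per label flip. If the constraint set is infeasible,
#' the error reports the minimal feasible `eps_fairness` found by bisection.
#'
#' @param features data.frame of numeric features (training rows).
#' @param labels binary 0/1 labels.
#' @param group binary group vector (1 = privileged).
#' @param eps_fairness bound on the transformed label-rate gap, default 0.05.
#' @param distortion_budget per-(x, y, s) expected-distortion bound, default 0.5.
#' @param fidelity_budget total-variation budget, default 0.1.
#' @param scheme a [discretization_scheme()]; fitted from the data when `NULL`.
#' @param bins,map_features passed to [discretization_scheme()] when fitting.
#' @param label_flip_weight distortion weight of a label flip, default 2.
#' @param solver_tol tolerance accepted on constraint slacks, default 1e-6.
#' @return class `mitigation_map`: the scheme, conditioning table, transition
#'   matrix `p_map` (rows = observed (cell, y, s), columns = (cell, y_hat)),
#'   achieved `objective`, implied per-group transformed label rates and gap,
#'   and constraint slacks.
#' @export
fit_mitigation <- function(features, labels, group,
                           eps_fairness = 0.05, distortion_budget = 0.5,
                           fidelity_budget = 0.1, scheme = NULL, bins = 3L,
                           map_features = NULL, label_flip_weight = 2,
                           solver_tol = 1e-6) {
  features <- as.data.frame(features)
  y <- as.integer(labels); s <- as.integer(group)
  stopifnot(length(y) == nrow(features), length(s) == nrow(features))
  if (!any(s == 0) || !any(s == 1)) stopf("both groups must be nonempty")
  if (is.null(scheme))
    scheme <- discretization_scheme(features, map_features = map_features,
                                    labels = y, bins = bins)
  ac <- assign_cells(scheme, features)
  sol <- solve_mitigation_lp(scheme, ac$cell, y, s, eps_fairness,
                             distortion_budget, fidelity_budget,
                             label_flip_weight)
  if (!sol$feasible) {
    eps_min <- bisect_feasible_eps(scheme, ac$cell, y, s, distortion_budget,
                                   fidelity_budget, label_flip_weight)
    stopf(paste0("mitigation LP infeasible at eps_fairness = %.4g; ",
                 "minimal feasible eps_fairness is approximately %.4g"),
          eps_fairness, eps_min)
  }
  structure(c(sol, list(
    scheme = scheme, eps_fairness = eps_fairness,
    distortion_budget = distortion_budget, fidelity_budget = fidelity_budget,
    label_flip_weight = label_flip_weight, solver_tol = solver_tol
  )), class = "mitigation_map")
}

## Build and solve the LP. Returns list(feasible, p_map, cond, outcomes,
## objective, implied_rates, slacks) with feasible = FALSE on solver failure.
solve_mitigation_lp <- function(scheme, cell, y, s, eps, dist_budget,
                                fid_budget, flip_w) {
  C <- nrow(scheme$cell_grid)
  H <- cell_hamming(scheme)
  outcomes <- data.frame(cell = rep(seq_len(C), 2),
                         yhat = rep(c(0L, 1L), each = C))
  O <- nrow(outcomes)

  cond <- as.data.frame(stats::aggregate(
    list(count = rep(1L, length(cell))),
    by = list(cell = cell, y = y, s = s), FUN = sum))
  K <- nrow(cond)
  n <- length(cell)
  P_cond <- cond$count / n
  P_s <- c(`0` = mean(s == 0), `1` = mean(s == 1))

  ## a zero distortion budget pins the map at the identity exactly; decide
  ## feasibility arithmetically instead of handing the solver a degenerate
  ## single-point polytope
  if (dist_budget == 0) {
    p_map <- matrix(0, K, O)
    for (k in seq_len(K))
      p_map[k, which(outcomes$cell == cond$cell[k] &
                     outcomes$yhat == cond$y[k])] <- 1
    implied <- implied_label_rates(p_map, cond, outcomes, P_cond, P_s)
    if (abs(implied$gap) > eps) return(list(feasible = FALSE))
    return(list(feasible = TRUE, p_map = p_map, cond = cond,
                outcomes = outcomes, objective = 0, implied_rates = implied,
                slacks = list(fairness = eps - abs(implied$gap),
                              distortion = 0, fidelity = fid_budget)))
  }

  ## distortion Delta(k, o)
  D <- matrix(0, K, O)
  for (k in seq_len(K)) {
    D[k, ] <- H[cond$cell[k], outcomes$cell] +
      flip_w * (outcomes$yhat != cond$y[k])
  }

  nv <- K * O          # transition probabilities, row-major by k
  nt <- O              # TV auxiliaries
  pid <- function(k, o) (k - 1L) * O + o

  cc <- c(as.vector(t(D * P_cond)), rep(0, nt))

  ## equalities: each conditioning row sums to 1
  Aeq <- matrix(0, K, nv + nt)
  for (k in seq_len(K)) Aeq[k, pid(k, seq_len(O))] <- 1
  beq <- rep(1, K)

  rows <- list(); rhs <- c()
  add_row <- function(r, b) { rows[[length(rows) + 1]] <<- r; rhs <<- c(rhs, b) }

  ## fairness: |r0 - r1| <= eps with r_s = sum_k P(k|s) sum_{o: yhat=1} p
  pos_o <- which(outcomes$yhat == 1)
  fair <- rep(0, nv + nt)
  for (k in seq_len(K)) {
    w <- P_cond[k] / P_s[as.character(cond$s[k])]
    sgn <- if (cond$s[k] == 0) 1 else -1
    fair[pid(k, pos_o)] <- fair[pid(k, pos_o)] + sgn * w
  }
  add_row(fair, eps); add_row(-fair, eps)

  ## per-conditioning distortion budget
  for (k in seq_len(K)) {
    r <- rep(0, nv + nt); r[pid(k, seq_len(O))] <- D[k, ]
    add_row(r, dist_budget)
  }

  ## fidelity: TV between transformed and original (cell, y) marginal
  p0 <- rep(0, O)
  for (k in seq_len(K)) {
    o <- which(outcomes$cell == cond$cell[k] & outcomes$yhat == cond$y[k])
    p0[o] <- p0[o] + P_cond[k]
  }
  for (o in seq_len(O)) {
    r <- rep(0, nv + nt)
    r[pid(seq_len(K), o)] <- P_cond
    r[nv + o] <- -1
    add_row(r, p0[o])          #  phat_o - t_o <= p0_o
    r2 <- -r; r2[nv + o] <- -1
    add_row(r2, -p0[o])        # -phat_o - t_o <= -p0_o
  }
  tv_row <- c(rep(0, nv), rep(1, nt))
  add_row(tv_row, 2 * fid_budget)

  A <- do.call(rbind, rows)
  res <- lp_solve_ridge(cc, A, rhs, Aeq, beq)
  if (is.null(res)) return(list(feasible = FALSE))

  x <- pmax(res$x, 0)
  p_map <- matrix(x[seq_len(nv)], K, O, byrow = TRUE)
  p_map <- p_map / rowSums(p_map)

  implied <- implied_label_rates(p_map, cond, outcomes, P_cond, P_s)
  phat <- as.vector(P_cond %*% p_map)
  slacks <- list(
    fairness = eps - abs(implied$gap),
    distortion = dist_budget - max(rowSums(p_map * D)),
    fidelity = fid_budget - 0.5 * sum(abs(phat - p0))
  )
  list(feasible = TRUE, p_map = p_map, cond = cond, outcomes = outcomes,
       objective = sum(P_cond * rowSums(p_map * D)),
       implied_rates = implied, slacks = slacks)
}

## Solve min c'x s.t. A x <= b, Aeq x = beq, x >= 0 as a ridge-regularized
## QP (quadprog dual active set). Returns NULL when the constraint set is
## infeasible.
lp_solve_ridge <- function(cc, A, b, Aeq, beq, lambda = 1e-8) {
  nv <- length(cc)
  Amat <- t(rbind(Aeq, -A, diag(nv)))
  bvec <- c(beq, -b, rep(0, nv))
  sol <- tryCatch(
    quadprog::solve.QP(diag(lambda, nv), -cc, Amat, bvec, meq = nrow(Aeq)),
    error = function(e) {
      if (grepl("inconsistent", conditionMessage(e))) NULL else stop(e)
    }
  )
  if (is.null(sol)) return(NULL)
  list(x = sol$solution, fval = sum(cc * sol$solution))
}

## transformed P(yhat = 1 | s) implied by the map and the empirical
## conditioning distribution
implied_label_rates <- function(p_map, cond, outcomes, P_cond, P_s) {
  pos_o <- outcomes$yhat == 1
  r <- c(`0` = 0, `1` = 0)
  for (k in seq_len(nrow(cond))) {
    sk <- as.character(cond$s[k])
    r[sk] <- r[sk] + P_cond[k] / P_s[sk] * sum(p_map[k, pos_o])
  }
  list(unprivileged = unname(r["0"]), privileged = unname(r["1"]),
       gap = unname(r["0"] - r["1"]))
}

bisect_feasible_eps <- function(scheme, cell, y, s, dist_budget, fid_budget,
                                flip_w, iters = 12) {
  lo <- 0; hi <- 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    ok <- solve_mitigation_lp(scheme, cell, y, s, mid, dist_budget,
                              fid_budget, flip_w)$feasible
    if (ok) hi <- mid else lo <- mid
  }
  hi
}

#' Apply a fitted mitigation map to rows
#'
#' Per row, samples `(x_hat, y_hat)` from the map given the row's
#' `(cell, y, s)` conditioning. When the sampled cell equals the original
#' cell the raw feature values pass through untouched (so the identity map
#' leaves rows unchanged); when a mapped feature's bin changes, the value is
#' realized as the new bin's representative (median). Rows outside the
#' scheme's support are clamped to the nearest cell (logged); a conditioning
#' never seen at fit time passes through unchanged (logged). Reproducible
#' under `seed`.
#'
#' @param map a [fit_mitigation()] result.
#' @param features data.frame of rows to transform.
#' @param labels,group binary vectors aligned with `features`.
#' @param seed integer seed.
#' @return list: `features` (transformed), `labels` (transformed), `log`
#'   (label flips and feature moves per group, clamped/unseen counts).
#' @export
apply_mitigation <- function(map, features, labels, group, seed = 1L) {
  features <- as.data.frame(features)
  y <- as.integer(labels); s <- as.integer(group)
  scheme <- map$scheme
  ac <- assign_cells(scheme, features)
  key <- paste(map$cond$cell, map$cond$y, map$cond$s)
  row_key <- paste(ac$cell, y, s)
  k_idx <- match(row_key, key)

  out_f <- features
  out_y <- y
  flips <- c(`0` = 0L, `1` = 0L)
  moves <- c(`0` = 0L, `1` = 0L)
  unseen <- sum(is.na(k_idx))
  O <- nrow(map$outcomes)

  ## sample outcomes independently per row, vectorized within conditioning
  o_draw <- rep(NA_integer_, nrow(features))
  with_seed(seed, {
    for (k in sort(unique(k_idx[!is.na(k_idx)]))) {
      rows <- which(!is.na(k_idx) & k_idx == k)
      o_draw[rows] <- sample.int(O, length(rows), replace = TRUE,
                                 prob = map$p_map[k, ])
    }
  })
  ## rows whose drawn outcome equals their identity outcome need no work
  C <- nrow(scheme$cell_grid)
  id_o <- ac$cell + C * y
  for (i in which(!is.na(o_draw) & o_draw != id_o)) {
    o <- o_draw[i]
    new_cell <- map$outcomes$cell[o]
    new_y <- map$outcomes$yhat[o]
    if (new_y != y[i]) {
      out_y[i] <- new_y
      flips[as.character(s[i])] <- flips[as.character(s[i])] + 1L
    }
    if (new_cell != ac$cell[i]) {
      old_bins <- scheme$cell_grid[ac$cell[i], ]
      new_bins <- scheme$cell_grid[new_cell, ]
      for (j in seq_along(scheme$map_features)) {
        if (new_bins[j] != old_bins[j]) {
          nm <- scheme$map_features[j]
          out_f[i, nm] <- scheme$representatives[[nm]][new_bins[j]]
        }
      }
      moves[as.character(s[i])] <- moves[as.character(s[i])] + 1L
    }
  }
  list(features = out_f, labels = out_y,
       log = list(label_flips = as.list(flips), feature_moves = as.list(moves),
                  clamped_rows = ac$clamped, unseen_conditionings = unseen,
                  seed = as.integer(seed)))
}

#' Fit-and-apply mitigation on a cohort's training rows
#'
#' Convenience wrapper honouring the pre-processing contract: the map is
#' fitted on training rows only and applied to training rows only; test rows
#' pass through untouched.
#'
#' @param ch a preprocessed cohort (binarized sensitive columns present).
#' @param spec the [sensitive_spec()] whose group the fairness constraint
#'   bounds.
#' @param plan a [split_cohort()] plan.
#' @param seed seed for the stochastic application step.
#' @param ... passed to [fit_mitigation()].
#' @return list: `cohort` (train rows transformed), `map`, `log`.
#' @export
mitigate_cohort <- function(ch, spec, plan, seed = 1L, ...) {
  feats <- exclude_sensitive_from_features(ch)
  y <- cohort_label(ch)
  g <- group_vector(ch, spec)
  ti <- plan$train_idx
  map <- fit_mitigation(feats[ti, , drop = FALSE], y[ti], g[ti], ...)
  ap <- apply_mitigation(map, feats[ti, , drop = FALSE], y[ti], g[ti],
                         seed = seed)
  df <- as.data.frame(ch)
  df[ti, names(ap$features)] <- ap$features
  df[ti, cols_by_role(ch, "label")] <- ap$labels
  out <- rebuild(ch, df)
  out <- append_log(out, "mitigate", ap$log)
  list(cohort = out, map = map, log = ap$log)
}

#' @export
print.mitigation_map <- function(x, ...) {
  cat(sprintf(
    "<mitigation_map> %d conditionings x %d outcomes; objective %.4f\n",
    nrow(x$cond), nrow(x$outcomes), x$objective))
  cat(sprintf("  implied label rates: unpriv %.4f, priv %.4f (gap % .4f, eps %.3f)\n",
              x$implied_rates$unprivileged, x$implied_rates$privileged,
              x$implied_rates$gap, x$eps_fairness))
  invisible(x)
}

#' Serialize a mitigation map to JSON
#' @param map a `mitigation_map`.
#' @param path output path.
#' @export
write_mitigation_map <- function(map, path) {
  out <- list(
    map_features = map$scheme$map_features,
    breaks = map$scheme$breaks,
    representatives = map$scheme$representatives,
    cond = map$cond, outcomes = map$outcomes,
    p_map = apply(map$p_map, 1, function(r) as.list(r)),
    objective = map$objective, implied_rates = map$implied_rates,
    slacks = map$slacks,
    config = list(eps_fairness = map$eps_fairness,
                  distortion_budget = map$distortion_budget,
                  fidelity_budget = map$fidelity_budget,
                  label_flip_weight = map$label_flip_weight)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
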