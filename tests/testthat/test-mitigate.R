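test_that("LP optimum on the 2x2x2 toy matches the exhaustive lattice oracle", {
  td <- toy_data()
  map <- fit_mitigation(data.frame(f = td$f), td$y, td$s,
                        eps_fairness = 0.10, distortion_budget = 0.5,
                        fidelity_budget = 1, scheme = toy_scheme(),
                        label_flip_weight = 2)
  ## independent oracle: rebuild conditioning table and distortion by hand
  cond <- aggregate(list(count = rep(1, nrow(td))),
                    by = list(cell = td$f + 1, y = td$y, s = td$s), FUN = sum)
  P_cond <- cond$count / nrow(td)
  outcomes <- expand.grid(cell = 1:2, yhat = 0:1)
  D <- matrix(0, 8, 4)
  for (k in 1:8) for (o in 1:4)
    D[k, o] <- (cond$cell[k] != outcomes$cell[o]) +
      2 * (cond$y[k] != outcomes$yhat[o])
  oracle <- toy_grid_oracle(cond, P_cond, D, eps = 0.10, dist_budget = 0.5)
  ## the toy is built so the continuous optimum sits on the lattice
  expect_equal(oracle, 0.2, tolerance = 1e-9)
  expect_equal(map$objective, oracle, tolerance = 1e-5)
  expect_lte(abs(map$implied_rates$gap), 0.10 + 1e-4)
})

test_that("already-fair input is left at zero distortion", {
  set.seed(21)
  n <- 600
  f <- data.frame(a = rnorm(n), b = rnorm(n))
  s <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.4)            # label independent of group
  map <- fit_mitigation(f, y, s, eps_fairness = 0.10)
  expect_lt(map$objective, 1e-6)
  expect_lte(abs(map$implied_rates$gap), 0.10 + 1e-4)
})

test_that("a hand-built identity map leaves rows unchanged", {
  td <- toy_data()
  sch <- toy_scheme()
  cond <- aggregate(list(count = rep(1, nrow(td))),
                    by = list(cell = td$f + 1, y = td$y, s = td$s), FUN = sum)
  outcomes <- expand.grid(cell = 1:2, yhat = 0:1)
  p_map <- matrix(0, nrow(cond), nrow(outcomes))
  for (k in seq_len(nrow(cond)))
    p_map[k, which(outcomes$cell == cond$cell[k] &
                   outcomes$yhat == cond$y[k])] <- 1
  map <- structure(list(scheme = sch, cond = cond, outcomes = outcomes,
                        p_map = p_map), class = "mitigation_map")
  ap <- apply_mitigation(map, data.frame(f = td$f), td$y, td$s, seed = 4)
  expect_identical(ap$features$f, td$f)
  expect_identical(ap$labels, as.integer(td$y))
  expect_equal(ap$log$label_flips, list(`0` = 0L, `1` = 0L))
})

test_that("application is reproducible under a fixed seed", {
  td <- toy_data()
  map <- fit_mitigation(data.frame(f = td$f), td$y, td$s,
                        eps_fairness = 0.10, fidelity_budget = 1,
                        scheme = toy_scheme())
  a <- apply_mitigation(map, data.frame(f = td$f), td$y, td$s, seed = 5)
  b <- apply_mitigation(map, data.frame(f = td$f), td$y, td$s, seed = 5)
  expect_identical(a, b)
  c <- apply_mitigation(map, data.frame(f = td$f), td$y, td$s, seed = 6)
  expect_false(identical(a$labels, c$labels))
})

test_that("empirical transformed label rates converge to the implied rates", {
  ## law-of-large-numbers check at n = 50,000
  set.seed(22)
  n <- 50000
  s <- rbinom(n, 1, 0.5)
  f <- data.frame(a = rnorm(n) + 0.8 * s, b = rnorm(n))
  y <- rbinom(n, 1, ifelse(s == 1, 0.3, 0.6))      # gap ~ 0.3
  map <- fit_mitigation(f, y, s, eps_fairness = 0.05)
  ap <- apply_mitigation(map, f, y, s, seed = 23)
  for (g in 0:1) {
    emp <- mean(ap$labels[s == g])
    imp <- if (g == 0) map$implied_rates$unprivileged else map$implied_rates$privileged
    se <- sqrt(imp * (1 - imp) / sum(s == g))
    expect_lt(abs(emp - imp), 3 * se)
  }
})

test_that("post-mitigation gap respects eps on a planted cohort", {
  ch <- generate_cohort(cohort_config(bias_strength = -0.3, seed = 31))
  pp <- preprocess_pipeline(ch, seed = 31)
  y <- cohort_label(pp$cohort)
  g <- group_vector(pp$cohort, default_sensitive_specs()$gender)
  fv <- exclude_sensitive_from_features(pp$cohort)
  ti <- pp$plan$train_idx
  expect_lt(spd(y[ti], g[ti]), -0.2)    # the planted disparity is present
  map <- fit_mitigation(fv[ti, ], y[ti], g[ti], eps_fairness = 0.05)
  expect_lte(abs(map$implied_rates$gap), 0.05 + 1e-4)
  ## constraint slacks within the documented tolerance
  expect_gte(map$slacks$fairness, -1e-4)
  expect_gte(map$slacks$distortion, -1e-4)
  expect_gte(map$slacks$fidelity, -1e-4)
  ## the sampled application shrinks the empirical disparity too
  ap <- apply_mitigation(map, fv[ti, ], y[ti], g[ti], seed = 32)
  expect_lt(abs(spd(ap$labels, g[ti])), 0.3)
  expect_lt(abs(spd(ap$labels, g[ti])) , abs(spd(y[ti], g[ti])))
})

test_that("mitigation never touches held-out rows", {
  ch <- generate_cohort(cohort_config(n_pd = 300, n_hc = 200,
                                      bias_strength = -0.2, seed = 33))
  pp <- preprocess_pipeline(ch, seed = 33)
  out <- mitigate_cohort(pp$cohort, default_sensitive_specs()$gender,
                         pp$plan, seed = 34)
  te <- pp$plan$test_idx
  expect_identical(plain_df(out$cohort)[te, ], plain_df(pp$cohort)[te, ])
})

test_that("tightening eps never decreases the optimal distortion", {
  td <- toy_data()
  prev <- -Inf
  for (eps in c(0.25, 0.15, 0.10, 0.05, 0.02)) {
    map <- fit_mitigation(data.frame(f = td$f), td$y, td$s,
                          eps_fairness = eps, fidelity_budget = 1,
                          scheme = toy_scheme())
    expect_gte(map$objective + 1e-9, prev)
    prev <- map$objective
  }
})

test_that("infeasible constraints report the minimal feasible eps", {
  td <- toy_data()
  err <- tryCatch(
    fit_mitigation(data.frame(f = td$f), td$y, td$s, eps_fairness = 0.05,
                   distortion_budget = 0, fidelity_budget = 1,
                   scheme = toy_scheme()),
    error = function(e) conditionMessage(e))
  expect_match(err, "infeasible")
  ## with zero distortion budget the map is frozen at identity, so the
  ## minimal feasible eps is the raw gap (0.3)
  eps_min <- as.numeric(sub(".*approximately ", "", err))
  expect_lt(abs(eps_min - 0.3), 0.02)
})

test_that("mitigation map serializes to JSON", {
  td <- toy_data()
  map <- fit_mitigation(data.frame(f = td$f), td$y, td$s,
                        eps_fairness = 0.10, fidelity_budget = 1,
                        scheme = toy_scheme())
  p <- file.path(tempdir(), "map.json")
  write_mitigation_map(map, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$objective, map$objective, tolerance = 1e-9)
  expect_equal(back$config$eps_fairness, 0.10)
  unlink(p)
})
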