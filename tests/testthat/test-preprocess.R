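test_that("cleaning removes duplicates and repairs text-coded numbers", {
  df <- data.frame(a = c("1.5", "3.5", "N/A", "1.5"),
                   b = c(2, 7, 9, 2),
                   race = c("White", "Non-White", "White", "White"),
                   label = c(1L, 0L, 1L, 1L),
                   stringsAsFactors = FALSE)
  ch <- cohort(df, c(a = "clinical", b = "clinical", race = "sensitive",
                     label = "label"))
  out <- clean(ch)
  expect_equal(nrow(out), 3)           # exact duplicate row dropped
  expect_type(out$a, "double")
  expect_equal(out$a, c(1.5, 3.5, NA))
  expect_identical(out$race, c("White", "Non-White", "White"))  # not coerced
  lg <- cohort_log(out)[[1]]
  expect_equal(lg$duplicates_removed, 1)
  expect_true("a" %in% lg$columns_coerced)
})

test_that("missing-token coercion matches the hand-enumerated table", {
  tokens <- c("", "NA", "N/A", "n/a", "na", "NaN", "nan", "NULL", "null",
              "?", ".")
  df <- data.frame(a = c(tokens, "2.5"), b = 1, label = 1L,
                   stringsAsFactors = FALSE)
  ch <- cohort(df, c(a = "clinical", b = "clinical", label = "label"))
  out <- clean(ch)
  expect_equal(out$a, c(rep(NA_real_, length(tokens)), 2.5))
})

test_that("missingness filter keeps features up to exactly the threshold", {
  n <- 100
  fracs <- c(f0 = 0, f10 = 0.10, f20 = 0.20, f30 = 0.30, f40 = 0.40, f50 = 0.50)
  clin <- as.data.frame(lapply(fracs, function(f) {
    x <- rnorm(n); x[seq_len(round(f * n))] <- NA; x
  }))
  ch <- make_cohort(clin, rep(0:1, 50))
  out <- drop_high_missingness(ch, 0.30)
  kept <- intersect(names(out), names(fracs))
  expect_setequal(kept, c("f0", "f10", "f20", "f30"))  # strict ">" rule
  expect_equal(names(drop_high_missingness(ch, 1.0))[1:6], names(fracs))
  ## sensitive and label columns survive any threshold
  expect_true("label" %in% names(out))
})

test_that("missingness filter errors when nothing survives", {
  clin <- data.frame(a = c(NA, NA, NA, 1), b = c(NA, NA, 1, NA))
  ch <- make_cohort(clin, c(0L, 1L, 0L, 1L))
  expect_error(drop_high_missingness(ch, 0.30), "cannot proceed")
})

test_that("imputation uses train-only medians and modes with smallest-value ties", {
  clin <- data.frame(num = c(1, 2, NA, 4))
  ch <- make_cohort(clin, c(0L, 1L, 0L, 1L))
  out <- impute(ch)
  expect_equal(out$num, c(1, 2, 2, 4))   # median of observed
  ## untouched when nothing is missing
  ch2 <- make_cohort(data.frame(num = 1:4 / 2), c(0L, 1L, 0L, 1L))
  expect_equal(impute(ch2)$num, 1:4 / 2)
  ## categorical mode with tie -> smallest
  df <- data.frame(x = 1, cat = c("A", "A", "B", NA), label = c(0L, 1L, 0L, 1L),
                   stringsAsFactors = FALSE)
  ch3 <- cohort(df, c(x = "clinical", cat = "sensitive", label = "label"))
  expect_equal(impute(ch3)$cat[4], "A")
  df$cat <- c("B", "A", NA, NA)
  ch4 <- cohort(df, c(x = "clinical", cat = "sensitive", label = "label"))
  expect_equal(impute(ch4)$cat[3:4], c("A", "A"))   # tie broken low
  ## fit scope: statistics come from training rows only
  clin5 <- data.frame(num = c(1, 1, NA, 100))
  ch5 <- make_cohort(clin5, c(0L, 1L, 0L, 1L))
  out5 <- impute(ch5, train_idx = c(1, 2))
  expect_equal(out5$num[3], 1)           # not influenced by row 4
  ## all-missing training feature is an error naming the feature
  expect_error(impute(make_cohort(data.frame(bad = c(NA, NA, 3)), c(0L, 1L, 1L)),
                      train_idx = 1:2), "bad")
})

test_that("min-max normalization follows the printed formula", {
  clin <- data.frame(y = c(2, 3, 6, 4))
  ch <- make_cohort(clin, c(0L, 1L, 0L, 1L))
  out <- minmax_normalize(ch)
  expect_equal(out$cohort$y, c(0, 0.25, 1, 0.5))    # (y - 2)/(6 - 2)
  expect_equal(unname(out$params$y_min["y"]), 2)
  expect_equal(unname(out$params$y_max["y"]), 6)
  ## custom target interval [c, d]
  out2 <- minmax_normalize(ch, range = c(-1, 1))
  expect_equal(out2$cohort$y, c(-1, -0.5, 1, 0))
  ## constant feature maps to c
  chc <- make_cohort(data.frame(y = rep(5, 4)), c(0L, 1L, 0L, 1L))
  expect_equal(minmax_normalize(chc)$cohort$y, rep(0, 4))
})

test_that("normalization fits on training rows and clips held-out rows", {
  clin <- data.frame(y = c(0, 10, 5, -3, 20))
  ch <- make_cohort(clin, c(0L, 1L, 0L, 1L, 1L))
  out <- minmax_normalize(ch, train_idx = 1:3)
  expect_equal(unname(out$params$y_max["y"]), 10)   # test rows never fitted
  expect_equal(out$cohort$y, c(0, 1, 0.5, 0, 1))    # rows 4, 5 clipped
  lg <- cohort_log(out$cohort)
  expect_equal(lg[[length(lg)]]$clipped_cells, 2)
  ## re-applying stored params is exact
  out2 <- minmax_normalize(ch, params = out$params)
  expect_equal(out2$cohort$y, out$cohort$y)
})

test_that("sensitive binarization applies the cut/category/passthrough rules", {
  df <- data.frame(x = rnorm(4), age = c(64.2, 59.9, 60, 41),
                   gender = c(1L, 0L, 1L, 0L),
                   race = c("White", "Non-White", "White", "White"),
                   label = c(1L, 0L, 1L, 0L), stringsAsFactors = FALSE)
  ch <- cohort(df, c(x = "clinical", age = "sensitive", gender = "sensitive",
                     race = "sensitive", label = "label"))
  out <- binarize_sensitive(ch)
  expect_equal(out$age_priv, c(0L, 1L, 0L, 1L))    # privileged = "<60"
  expect_equal(out$race_priv, c(1L, 0L, 1L, 1L))   # privileged = White
  expect_equal(out$gender_priv, df$gender)         # 0/1 passthrough
  expect_true(all(roles(out)[c("age_priv", "race_priv", "gender_priv")]
                  == "sensitive_bin"))
  ## unmapped category errors listing the offender
  df$race[2] <- NA
  ch2 <- cohort(df, roles(ch))
  expect_error(binarize_sensitive(ch2), "race")
})

test_that("feature view excludes sensitive columns but keeps a leak column", {
  clin <- as.data.frame(matrix(rnorm(40), 4, 10,
                               dimnames = list(NULL, paste0("f", 1:10))))
  sens <- data.frame(age = c(50, 70, 60, 40), gender = c(1L, 0L, 1L, 0L),
                     race = rep("White", 4), stringsAsFactors = FALSE)
  ch <- make_cohort(clin, c(1L, 0L, 1L, 0L), sens)
  expect_equal(ncol(exclude_sensitive_from_features(ch)), 10)
  lk <- inject_leak_feature(ch, sens$gender, attack_config("leak", seed = 5))
  fv <- exclude_sensitive_from_features(lk$data)
  expect_true("leak_s" %in% names(fv))
  expect_equal(ncol(fv), 11)
  ## feature view round-trips through CSV with identical column order
  p <- file.path(tempdir(), "fv.csv")
  utils::write.csv(fv, p, row.names = FALSE)
  expect_identical(names(utils::read.csv(p)), names(fv))
  unlink(p)
})

test_that("stratified split holds out 20% per class with exact CV folds", {
  clin <- data.frame(x = rnorm(1000))
  ch <- make_cohort(clin, rep(c(1L, 0L), times = c(600, 400)))
  plan <- split_cohort(ch, seed = 31)
  expect_length(plan$test_idx, 200)
  y <- cohort_label(ch)
  expect_lte(abs(sum(y[plan$test_idx]) - 120), 1)
  ## train/test disjoint and exhaustive
  expect_setequal(c(plan$train_idx, plan$test_idx), seq_len(1000))
  expect_length(intersect(plan$train_idx, plan$test_idx), 0)
  ## folds partition the training rows; class balance within +-1 per fold
  expect_equal(sort(unique(plan$folds)), 1:5)
  expect_length(plan$folds, length(plan$train_idx))
  pos_per_fold <- tapply(y[plan$train_idx], plan$folds, sum)
  expect_lte(diff(range(pos_per_fold)), 1)
  ## determinism
  expect_identical(split_cohort(ch, seed = 31), plan)
  ## class with fewer than 5 training members errors
  tiny <- make_cohort(data.frame(x = rnorm(10)), c(rep(0L, 7), rep(1L, 3)))
  expect_error(split_cohort(tiny), "fewer than")
})

test_that("pipeline stages are idempotent and never fit on test rows", {
  ch <- generate_cohort(cohort_config(n_pd = 150, n_hc = 100,
                                      missing_frac = 0.1, seed = 21))
  pp <- preprocess_pipeline(ch, seed = 21)
  fv <- exclude_sensitive_from_features(pp$cohort)
  expect_false(anyNA(fv))
  tr <- fv[pp$plan$train_idx, ]
  expect_true(all(vapply(tr, min, 0) >= 0) && all(vapply(tr, max, 0) <= 1))
  expect_true(all(vapply(fv, min, 0) >= 0) && all(vapply(fv, max, 0) <= 1))
  ## idempotence on its own output
  again <- clean(pp$cohort)
  expect_equal(plain_df(again), plain_df(pp$cohort))
  imp2 <- impute(pp$cohort, train_idx = pp$plan$train_idx)
  expect_equal(plain_df(imp2), plain_df(pp$cohort))
  ## leakage guard: distorting test rows must not move fitted statistics
  df2 <- as.data.frame(ch)
  te <- pp$plan$test_idx  # same labels + seed give the same plan
  for (nm in names(exclude_sensitive_from_features(ch)))
    df2[te, nm] <- df2[te, nm] * 1000 + 500
  ch2 <- cohort(df2, roles(ch))
  pp2 <- preprocess_pipeline(ch2, seed = 21)
  expect_equal(pp2$norm_params$y_min, pp$norm_params$y_min, tolerance = 1e-10)
  expect_equal(pp2$norm_params$y_max, pp$norm_params$y_max, tolerance = 1e-10)
})
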