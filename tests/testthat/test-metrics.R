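test_that("group confusion counts match hand enumeration", {
  ## four rows enumerated by hand:
  ## row1 g0: pred 1 label 1 -> TP; row2 g0: pred 0 label 0 -> TN
  ## row3 g1: pred 1 label 0 -> FP; row4 g1: pred 1 label 1 -> TP
  gc <- group_confusion(c(1, 0, 1, 1), c(1, 0, 0, 1), c(0, 0, 1, 1))
  u <- gc[gc$group == "unprivileged", ]
  p <- gc[gc$group == "privileged", ]
  expect_equal(c(u$TP, u$TN, u$FP, u$FN), c(1, 1, 0, 0))
  expect_equal(c(p$TP, p$TN, p$FP, p$FN), c(1, 0, 1, 0))
  expect_equal(u$n + p$n, 4)

  perfect <- group_confusion(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))
  inverted <- group_confusion(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_true(all(inverted$TP == 0) && all(inverted$TN == 0))
  expect_error(group_confusion(c(1, 0), c(1, 0, 1), c(0, 0, 1)), "mismatch")
})

test_that("group rates follow the printed formulas with NA for empty denominators", {
  gc <- data.frame(group = "unprivileged", TP = 3, TN = 5, FP = 2, FN = 1, n = 11)
  r <- group_rates(gc)
  expect_equal(r$TPR, 0.75)           # 3 / (3 + 1)
  expect_equal(r$TNR, 5 / 7)
  expect_equal(r$FDR, 2 / 5)
  expect_equal(r$NPV, 5 / 6)
  gc0 <- data.frame(group = "privileged", TP = 0, TN = 4, FP = 0, FN = 0, n = 4)
  r0 <- group_rates(gc0)
  expect_true(is.na(r0$TPR) && is.na(r0$FNR))   # undefined, not silent 0
  expect_equal(r0$TNR, 1)
})

test_that("SPD, DI, EOD, AAOD reproduce the hand-worked examples", {
  ## rates 0.5 (unpriv) vs 1.0 (priv)
  pred <- c(1, 0, 1, 1); grp <- c(0, 0, 1, 1)
  expect_equal(spd(pred, grp), -0.5)
  expect_equal(disparate_impact(pred, grp), 0.5)
  expect_equal(spd(c(1, 0, 1, 0), c(0, 0, 1, 1)), 0)
  expect_equal(disparate_impact(c(1, 0, 1, 0), c(0, 0, 1, 1)), 1)
  ## TPRs 0.6 (unpriv) vs 0.9 (priv) from hand-built confusions
  lab <- c(rep(1, 10), rep(1, 10))
  grp2 <- c(rep(0, 10), rep(1, 10))
  prd <- c(rep(1, 6), rep(0, 4), rep(1, 9), 0)
  expect_equal(eod(prd, lab, grp2), -0.3)
  ## EOD invariant to adding negative-label rows
  expect_equal(eod(c(prd, 1, 0), c(lab, 0, 0), c(grp2, 0, 1)), -0.3)
  ## AAOD magnitude: |dFPR| = 0.1, |dTPR| = 0.3 -> 0.2
  lab3 <- c(rep(1, 20), rep(0, 20))
  grp3 <- rep(c(rep(0, 10), rep(1, 10)), 2)
  prd3 <- c(rep(1, 6), rep(0, 4), rep(1, 9), 0,          # TPR 0.6 vs 0.9
            rep(1, 3), rep(0, 7), rep(1, 2), rep(0, 8))  # FPR 0.3 vs 0.2
  a <- aaod(prd3, lab3, grp3)
  expect_equal(attr(a, "magnitude"), 0.2)
  expect_equal(as.numeric(a), -0.2)    # sign follows dTPR < 0
  ## identical group confusions -> 0
  expect_equal(as.numeric(aaod(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 0, 1, 1))), 0)
})

test_that("group loss disparity equals the accuracy gap under 0-1 loss", {
  ## group error rates 0.10 vs 0.35
  n <- 100
  lab <- rep(0, 2 * n); grp <- rep(c(1, 0), each = n)
  prd <- c(rep(1, 10), rep(0, 90), rep(1, 35), rep(0, 65))
  expect_equal(group_loss_disparity(prd, lab, grp), 0.25)
  ## parity case
  expect_equal(group_loss_disparity(c(1, 0, 1, 0), c(0, 0, 0, 0), c(0, 0, 1, 1)), 0)
  ## 0-1 disparity == |accuracy gap|
  set.seed(5)
  for (i in 1:20) {
    tr <- random_triple(60)
    acc_gap <- abs(mean(tr$pred[tr$group == 1] == tr$label[tr$group == 1]) -
                   mean(tr$pred[tr$group == 0] == tr$label[tr$group == 0]))
    expect_equal(group_loss_disparity(tr$pred, tr$label, tr$group), acc_gap)
  }
  ## cross-entropy variant is nonnegative and finite on scores
  set.seed(6)
  s <- runif(50); l <- rbinom(50, 1, 0.5); g <- rbinom(50, 1, 0.5)
  d <- group_loss_disparity(s, l, g, loss = "cross_entropy")
  expect_gte(d, 0); expect_true(is.finite(d))
})

test_that("all metrics agree with the brute-force oracle on random triples", {
  set.seed(11)
  for (i in 1:200) {
    tr <- random_triple(30)
    gc <- group_confusion(tr$pred, tr$label, tr$group)
    for (g in 0:1) {
      ocf <- oracle_confusion(tr$pred, tr$label, tr$group, g)
      row <- gc[gc$group == if (g == 1) "privileged" else "unprivileged", ]
      expect_equal(unname(c(row$TP, row$TN, row$FP, row$FN)), unname(ocf))
      orr <- oracle_rates(ocf)
      impl <- group_rates(row)
      for (m in names(orr))
        expect_equal(unname(impl[[sub("\\..*", "", m)]]), unname(orr[m]))
    }
    expect_equal(spd(tr$pred, tr$group), oracle_spd(tr$pred, tr$group))
    expect_equal(disparate_impact(tr$pred, tr$group), oracle_di(tr$pred, tr$group))
    expect_equal(eod(tr$pred, tr$label, tr$group),
                 oracle_eod(tr$pred, tr$label, tr$group))
    a <- aaod(tr$pred, tr$label, tr$group)
    if (!is.na(a))
      expect_equal(attr(a, "magnitude"),
                   oracle_aaod_mag(tr$pred, tr$label, tr$group))
  }
})

test_that("algebraic identities and symmetries hold", {
  set.seed(13)
  for (i in 1:50) {
    tr <- random_triple(50)
    gc <- group_confusion(tr$pred, tr$label, tr$group)
    r <- group_rates(gc)
    for (j in 1:2) {
      if (!is.na(r$TPR[j])) expect_equal(r$TPR[j] + r$FNR[j], 1)
      if (!is.na(r$TNR[j])) expect_equal(r$TNR[j] + r$FPR[j], 1)
      if (!is.na(r$PPV[j])) expect_equal(r$PPV[j] + r$FDR[j], 1)
      if (!is.na(r$NPV[j])) expect_equal(r$NPV[j] + r$FOR[j], 1)
    }
    ## DI = 1 + SPD / P(pred = 1 | priv)
    s <- spd(tr$pred, tr$group); di <- disparate_impact(tr$pred, tr$group)
    pp <- mean(tr$pred[tr$group == 1] == 1)
    if (!is.na(di)) expect_equal(di, 1 + s / pp)
    expect_lte(abs(s), 1)
    ## permutation invariance
    perm <- sample(length(tr$pred))
    expect_equal(spd(tr$pred[perm], tr$group[perm]), s)
    expect_equal(eod(tr$pred[perm], tr$label[perm], tr$group[perm]),
                 eod(tr$pred, tr$label, tr$group))
    ## privileged-swap: SPD and EOD negate, DI inverts, AAOD magnitude fixed
    sw <- 1 - tr$group
    expect_equal(spd(tr$pred, sw), -s)
    e <- eod(tr$pred, tr$label, tr$group)
    if (!is.na(e)) expect_equal(eod(tr$pred, tr$label, sw), -e)
    di_sw <- disparate_impact(tr$pred, sw)
    if (!is.na(di) && !is.na(di_sw) && di > 0) expect_equal(di_sw, 1 / di)
    a <- aaod(tr$pred, tr$label, tr$group)
    if (!is.na(a))
      expect_equal(attr(aaod(tr$pred, tr$label, sw), "magnitude"),
                   attr(a, "magnitude"))
  }
})

test_that("empty groups yield the undefined marker, never zero", {
  expect_true(is.na(spd(c(1, 0), c(1, 1))))
  expect_true(is.na(disparate_impact(c(0, 0, 1), c(1, 1, 0))))  # priv rate 0
  expect_true(is.na(eod(c(1, 0), c(0, 0), c(0, 1))))            # no positives
})

test_that("bias_report bundles metrics with the sign convention recorded", {
  set.seed(17)
  tr <- random_triple(80)
  br <- bias_report(tr$pred, tr$label, tr$group, attribute = "gender")
  expect_equal(br$SPD, spd(tr$pred, tr$group))
  expect_equal(br$EOD, eod(tr$pred, tr$label, tr$group))
  expect_match(br$convention, "unprivileged minus privileged")
  expect_equal(br$n_privileged + br$n_unprivileged, 80)
  expect_s3_class(br$rates, "data.frame")
})
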