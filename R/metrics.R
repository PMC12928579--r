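## Group confusion counts, the eight per-group rates, and the four bias
## metrics. Convention throughout: `group` is binary with 1 = privileged,
## 0 = unprivileged, and signed metrics are oriented unprivileged minus
## privileged. Zero denominators yield NA (an explicit undefined marker),
## never a silent 0.

check_triple <- function(pred, label = NULL, group = NULL) {
  n <- length(pred)
  if (!is_binary01(pred)) stopf("pred must be binary 0/1")
  if (!is.null(label)) {
    if (length(label) != n) stopf("length mismatch: pred %d vs label %d", n, length(label))
    if (!is_binary01(label)) stopf("label must be binary 0/1")
  }
  if (!is.null(group)) {
    if (length(group) != n) stopf("length mismatch: pred %d vs group %d", n, length(group))
    if (!is_binary01(group)) stopf("group must be binary 0/1")
  }
  invisible(TRUE)
}

rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-group confusion counts
#'
#' @param pred,label,group binary 0/1 vectors of equal length
#'   (group: 1 = privileged).
#' @return class `group_confusion`: a data.frame with one row per group
#'   (`unprivileged`, `privileged`) and columns `TP`, `TN`, `FP`, `FN`, `n`.
#' @export
group_confusion <- function(pred, label, group) {
  check_triple(pred, label, group)
  one <- function(g) {
    i <- group == g
    data.frame(
      group = if (g == 1) "privileged" else "unprivileged",
      TP = sum(pred[i] == 1 & label[i] == 1),
      TN = sum(pred[i] == 0 & label[i] == 0),
      FP = sum(pred[i] == 1 & label[i] == 0),
      FN = sum(pred[i] == 0 & label[i] == 1),
      n = sum(i)
    )
  }
  structure(rbind(one(0), one(1)), class = c("group_confusion", "data.frame"))
}

#' The eight per-group rates from confusion counts
#'
#' TPR, TNR, FPR, FNR, FDR, FOR, PPV, NPV by their standard definitions
#' (sensitivity TP/(TP+FN), specificity TN/(TN+FP), and so on). A rate with a
#' zero denominator is `NA`.
#'
#' @param gc a [group_confusion()].
#' @return data.frame, one row per group, columns `group` plus the eight rates.
#' @export
group_rates <- function(gc) {
  out <- do.call(rbind, lapply(seq_len(nrow(gc)), function(i) {
    r <- gc[i, ]
    data.frame(
      group = r$group,
      TPR = rate(r$TP, r$TP + r$FN),
      TNR = rate(r$TN, r$TN + r$FP),
      FPR = rate(r$FP, r$FP + r$TN),
      FNR = rate(r$FN, r$FN + r$TP),
      FDR = rate(r$FP, r$FP + r$TP),
      FOR = rate(r$FN, r$FN + r$TN),
      PPV = rate(r$TP, r$TP + r$FP),
      NPV = rate(r$TN, r$TN + r$FN)
    )
  }))
  rownames(out) <- NULL
  out
}

pos_rate <- function(pred, group, g) {
  i <- group == g
  if (!any(i)) NA_real_ else mean(pred[i] == 1)
}

#' Statistical parity difference
#'
#' `P(pred = 1 | unprivileged) - P(pred = 1 | privileged)`; 0 means parity.
#'
#' @inheritParams group_confusion
#' @return signed proportion in `[-1, 1]`, `NA` if a group is empty.
#' @export
spd <- function(pred, group) {
  check_triple(pred, group = group)
  pos_rate(pred, group, 0) - pos_rate(pred, group, 1)
}

#' Disparate impact
#'
#' `P(pred = 1 | unprivileged) / P(pred = 1 | privileged)`; 1 means parity.
#' `NA` if a group is empty or the privileged positive rate is 0.
#'
#' @inheritParams group_confusion
#' @export
disparate_impact <- function(pred, group) {
  check_triple(pred, group = group)
  pp <- pos_rate(pred, group, 1)
  pu <- pos_rate(pred, group, 0)
  if (is.na(pp) || is.na(pu) || pp == 0) return(NA_real_)
  pu / pp
}

group_tpr <- function(pred, label, group, g) {
  i <- group == g & label == 1
  if (!any(i)) NA_real_ else mean(pred[i] == 1)
}

group_fpr <- function(pred, label, group, g) {
  i <- group == g & label == 0
  if (!any(i)) NA_real_ else mean(pred[i] == 1)
}

#' Equal opportunity difference
#'
#' `TPR(unprivileged) - TPR(privileged)`; 0 means equal opportunity. `NA` if
#' a group has no positive-label rows.
#'
#' @inheritParams group_confusion
#' @export
eod <- function(pred, label, group) {
  check_triple(pred, label, group)
  group_tpr(pred, label, group, 0) - group_tpr(pred, label, group, 1)
}

#' Average absolute odds difference
#'
#' Magnitude `(|dFPR| + |dTPR|) / 2` where `d` is the unprivileged-minus-
#' privileged difference; 0 means equalized odds. The returned value is
#' signed, `sign(dTPR) * magnitude`, so that reports carry the direction of
#' the opportunity gap; the nonnegative magnitude is available via
#' `attr(, "magnitude")`.
#'
#' @inheritParams group_confusion
#' @export
aaod <- function(pred, label, group) {
  check_triple(pred, label, group)
  dtpr <- group_tpr(pred, label, group, 0) - group_tpr(pred, label, group, 1)
  dfpr <- group_fpr(pred, label, group, 0) - group_fpr(pred, label, group, 1)
  if (is.na(dtpr) || is.na(dfpr)) return(NA_real_)
  mag <- (abs(dfpr) + abs(dtpr)) / 2
  structure(if (dtpr < 0) -mag else mag, magnitude = mag)
}

#' Between-group gap in mean prediction loss
#'
#' `|E[L | group = 1] - E[L | group = 0]|` with `L` either 0-1 loss on the
#' thresholded prediction or cross-entropy on the score. Under 0-1 loss this
#' equals the absolute accuracy gap between groups; it quantifies the
#' disparity induced by label leakage or poisoning.
#'
#' @param scores predicted scores in `[0, 1]` (for 0-1 loss, already
#'   thresholded predictions are also accepted).
#' @param label,group binary 0/1 vectors (group: 1 = privileged).
#' @param loss `"zero_one"` or `"cross_entropy"`.
#' @param threshold decision threshold for 0-1 loss, default 0.5.
#' @return nonnegative real, `NA` if a group is empty.
#' @export
group_loss_disparity <- function(scores, label, group,
                                 loss = c("zero_one", "cross_entropy"),
                                 threshold = 0.5) {
  loss <- match.arg(loss)
  if (length(scores) != length(label) || length(scores) != length(group))
    stopf("length mismatch")
  L <- switch(loss,
    zero_one = as.numeric((scores >= threshold) != (label == 1)),
    cross_entropy = {
      p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
      -(label * log(p) + (1 - label) * log(1 - p))
    }
  )
  if (!any(group == 0) || !any(group == 1)) return(NA_real_)
  abs(mean(L[group == 1]) - mean(L[group == 0]))
}

#' Full bias report for one prediction set and sensitive attribute
#'
#' Bundles SPD, DI, EOD, AAOD (signed and magnitude), group sizes and the
#' sign convention, together with per-group confusion counts and rates.
#'
#' @inheritParams group_confusion
#' @param attribute name recorded for the sensitive attribute.
#' @return class `bias_report` (a list).
#' @export
bias_report <- function(pred, label, group, attribute = "sensitive") {
  gc <- group_confusion(pred, label, group)
  aa <- aaod(pred, label, group)
  structure(list(
    attribute = attribute,
    SPD = spd(pred, group),
    DI = disparate_impact(pred, group),
    EOD = eod(pred, label, group),
    AAOD = as.numeric(aa),
    AAOD_magnitude = attr(aa, "magnitude") %||% NA_real_,
    n_unprivileged = sum(group == 0),
    n_privileged = sum(group == 1),
    convention = "unprivileged minus privileged; group 1 = privileged",
    confusion = gc,
    rates = group_rates(gc)
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> attribute: %s (n_unpriv %d, n_priv %d)\n",
              x$attribute, x$n_unprivileged, x$n_privileged))
  cat(sprintf("  SPD % .4f  DI %s  EOD % .4f  AAOD % .4f\n",
              x$SPD, ifelse(is.na(x$DI), "NA", sprintf("%.4f", x$DI)),
              x$EOD, x$AAOD))
  invisible(x)
}
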