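#' Clinical feature specification emulating the PPMI baseline visit
#'
#' Group-conditional means for the case (PD) and control (HC) classes and a
#' within-group standard deviation per clinical feature, taken from the
#' published baseline-visit cohort summary (smell identification, semantic
#' fluency, REM-sleep behaviour, sleepiness, cognition, depression, motor
#' scales, Hoehn & Yahr stage, daily-living ability, fatigue, education).
#' Standard deviations are floored at 0.1 so every feature keeps spread.
#'
#' @return `data.frame` with columns `name`, `mean_pd`, `mean_hc`, `sd`.
#' @export
default_feature_specs <- function() {
  specs <- data.frame(
    name = c("education", "upsit", "semantic_fluency", "rbd_questionnaire",
             "ess", "moca", "gds15", "updrs1", "updrs2", "updrs3",
             "hy_stage", "schwab_england", "fss"),
    mean_pd = c(15.47, 5.66, 28.43, 0.26, 0.82, 1.07, 0.36, 0.57, 0.49, 3.30,
                1.66, 90.40, 0.78),
    mean_hc = c(16.95, 7.80, 30.36, 0.22, 0.72, 1.03, 0.34, 0.44, 0.00, 2.90,
                0.00, 96.90, 0.53),
    sd = c(1.05, 1.51, 1.36, 0.03, 0.07, 0.03, 0.01, 0.09, 0.35, 0.28,
           1.17, 4.60, 0.18),
    stringsAsFactors = FALSE
  )
  specs$sd <- pmax(specs$sd, 0.1)
  specs
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published baseline-visit cohort constitution:
#' 648 cases / 434 controls, 391 males among cases and 202 among controls
#' (stored as fractions; allocation is exact), case/control mean ages
#' 64.23 / 62.83 years, race skewed toward White, and the group-conditional
#' clinical feature means of [default_feature_specs()].
#'
#' @param n_pd,n_hc class sizes (cases, controls).
#' @param male_frac_pd,male_frac_hc male fraction within each class.
#' @param age_mean_pd,age_mean_hc,age_sd age distribution parameters (years);
#'   ages are truncated-Gaussian on `age_range`.
#' @param age_range truncation interval for age, years.
#' @param race_white_frac fraction of participants recorded as White.
#' @param feature_specs `data.frame(name, mean_pd, mean_hc, sd)`.
#' @param missing_frac per-feature fraction of cells blanked completely at
#'   random (MCAR), in `[0, 1]`.
#' @param bias_strength signed shift planted into group label base rates via
#'   [plant_outcome_bias()]; 0 plants nothing.
#' @param bias_attribute sensitive attribute the planted bias refers to.
#' @param seed integer seed; the full cohort is byte-reproducible under it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_pd = 648L, n_hc = 434L,
                          male_frac_pd = 391 / 648, male_frac_hc = 202 / 434,
                          age_mean_pd = 64.23, age_mean_hc = 62.83, age_sd = 9,
                          age_range = c(30, 95),
                          race_white_frac = 0.9,
                          feature_specs = default_feature_specs(),
                          missing_frac = 0,
                          bias_strength = 0,
                          bias_attribute = "gender",
                          seed = 4765416L) {
  cfg <- list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
    male_frac_pd = male_frac_pd, male_frac_hc = male_frac_hc,
    age_mean_pd = age_mean_pd, age_mean_hc = age_mean_hc, age_sd = age_sd,
    age_range = age_range, race_white_frac = race_white_frac,
    feature_specs = feature_specs, missing_frac = missing_frac,
    bias_strength = bias_strength, bias_attribute = bias_attribute,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_pd <= 0) stopf("configuration error: n_pd must be > 0")
  if (cfg$n_hc <= 0) stopf("configuration error: n_hc must be > 0")
  for (f in c("male_frac_pd", "male_frac_hc", "race_white_frac", "missing_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("configuration error: %s must lie in [0, 1]", f)
  if (cfg$age_sd <= 0) stopf("configuration error: age_sd must be > 0")
  fs <- cfg$feature_specs
  if (!all(c("name", "mean_pd", "mean_hc", "sd") %in% names(fs)))
    stopf("configuration error: feature_specs lacks required columns")
  if (any(fs$sd <= 0)) stopf("configuration error: feature_specs sd must be > 0")
  if (round(cfg$male_frac_pd * cfg$n_pd) > cfg$n_pd)
    stopf("configuration error: male_frac_pd implies more males than cases")
  invisible(cfg)
}

## inverse-CDF sampling from a Gaussian truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic PPMI-like cohort
#'
#' Class sizes, sex-within-class counts and the race marginal are realized by
#' exact allocation (rounded counts assigned to randomly chosen rows), not by
#' per-row sampling, so the default configuration reproduces the published
#' cohort constitution exactly. Clinical features are drawn from
#' group-conditional Gaussians; ages from truncated Gaussians; missing cells
#' are inserted completely at random at `missing_frac` per feature. The whole
#' cohort is reproducible byte-for-byte under `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a [cohort()] with roles: clinical features, sensitive
#'   (`age`, `gender`, `race`), and `label`.
#' @export
#' @examples
#' ch <- generate_cohort(cohort_config())
#' table(cohort_label(ch))  # 434 controls, 648 cases
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_pd + config$n_hc
    label <- c(rep(1L, config$n_pd), rep(0L, config$n_hc))

    ## exact sex allocation within class
    m_pd <- as.integer(round(config$male_frac_pd * config$n_pd))
    m_hc <- as.integer(round(config$male_frac_hc * config$n_hc))
    gender <- integer(n)
    gender[sample(which(label == 1), m_pd)] <- 1L
    gender[sample(which(label == 0), m_hc)] <- 1L

    ## exact race marginal allocation
    race <- rep("Non-White", n)
    race[sample.int(n, as.integer(round(config$race_white_frac * n)))] <- "White"

    age <- numeric(n)
    age[label == 1] <- rtruncnorm(config$n_pd, config$age_mean_pd, config$age_sd,
                                  config$age_range[1], config$age_range[2])
    age[label == 0] <- rtruncnorm(config$n_hc, config$age_mean_hc, config$age_sd,
                                  config$age_range[1], config$age_range[2])

    fs <- config$feature_specs
    feats <- lapply(seq_len(nrow(fs)), function(i) {
      x <- numeric(n)
      x[label == 1] <- stats::rnorm(config$n_pd, fs$mean_pd[i], fs$sd[i])
      x[label == 0] <- stats::rnorm(config$n_hc, fs$mean_hc[i], fs$sd[i])
      x
    })
    names(feats) <- fs$name

    if (config$missing_frac > 0) {
      for (nm in names(feats)) {
        k <- as.integer(round(config$missing_frac * n))
        if (k > 0) feats[[nm]][sample.int(n, k)] <- NA_real_
      }
    }

    df <- data.frame(feats, age = age, gender = gender, race = race,
                     label = label, stringsAsFactors = FALSE)
    ## shuffle row order so class blocks are not contiguous
    df <- df[sample.int(n), , drop = FALSE]
    rownames(df) <- NULL

    rl <- c(stats::setNames(rep("clinical", nrow(fs)), fs$name),
            age = "sensitive", gender = "sensitive", race = "sensitive",
            label = "label")
    ch <- cohort(df, rl)
    ch <- append_log(ch, "generate", list(
      seed = config$seed, n_pd = config$n_pd, n_hc = config$n_hc,
      male_pd = m_pd, male_hc = m_hc
    ))
    if (config$bias_strength != 0) {
      spec <- default_sensitive_specs()[[config$bias_attribute]]
      if (is.null(spec)) stopf("configuration error: unknown bias_attribute '%s'",
                               config$bias_attribute)
      ch <- plant_outcome_bias(ch, spec, config$bias_strength,
                               seed = derive_seed(config$seed, 1))
      ## keep clinical features consistent with the relabelled outcome: rows
      ## whose label changed get their features redrawn from the
      ## group-conditional distribution of the new class (missing-cell
      ## positions are preserved), so the planted bias links groups to label
      ## base rates without injecting feature-label noise
      lg <- cohort_log(ch)
      flipped <- lg[[length(lg)]]$flipped_rows
      if (length(flipped)) {
        df2 <- as.data.frame(ch)
        y2 <- cohort_label(ch)
        set.seed(derive_seed(config$seed, 2))
        for (i in seq_len(nrow(fs))) {
          nm <- fs$name[i]
          mu <- ifelse(y2[flipped] == 1, fs$mean_pd[i], fs$mean_hc[i])
          newv <- stats::rnorm(length(flipped), mu, fs$sd[i])
          newv[is.na(df2[flipped, nm])] <- NA_real_
          df2[flipped, nm] <- newv
        }
        ch <- rebuild(ch, df2)
      }
    }
    ch
  })
}

#' Plant a known outcome-bias into a cohort's labels
#'
#' Relabels a minimal random subset of participants so that the label base-rate
#' gap `P(label = 1 | unprivileged) - P(label = 1 | privileged)` equals
#' `bias_strength` (within the +-1/group-size resolution of integer counts),
#' while preserving the total positive count exactly. This gives downstream
#' mitigation tests a ground-truth disparity to recover. `bias_strength = 0`
#' is a no-op: the cohort is returned unchanged even if a natural gap exists.
#'
#' @param ch a cohort.
#' @param spec a [sensitive_spec()] defining the two groups.
#' @param bias_strength signed target gap (unprivileged minus privileged).
#' @param seed integer seed for the random choice of flipped rows.
#' @return the cohort with relabelled rows; the flip log (flipped row indices,
#'   direction, per-group counts) is appended to the audit log.
#' @export
plant_outcome_bias <- function(ch, spec, bias_strength, seed = 1L) {
  if (bias_strength == 0) return(ch)
  g <- group_vector(ch, spec)
  y <- cohort_label(ch)
  n_u <- sum(g == 0); n_p <- sum(g == 1)
  if (n_u == 0 || n_p == 0) stopf("both groups must be nonempty")
  P <- sum(y)
  N <- n_u + n_p
  ## target rates: p_u - p_p = bias_strength, n_u*p_u + n_p*p_p = P
  p_p <- (P - n_u * bias_strength) / N
  p_u <- p_p + bias_strength
  if (p_p < 0 || p_p > 1 || p_u < 0 || p_u > 1) {
    rng <- p_p_range(P, n_u, n_p)
    stopf("unattainable bias_strength %.3f: feasible range is [%.3f, %.3f]",
          bias_strength, rng$lo, rng$hi)
  }
  k_p <- as.integer(round(p_p * n_p))
  k_u <- P - k_p
  if (k_u < 0 || k_u > n_u) {
    rng <- p_p_range(P, n_u, n_p)
    stopf("unattainable bias_strength %.3f: feasible range is [%.3f, %.3f]",
          bias_strength, rng$lo, rng$hi)
  }
  with_seed(seed, {
    y2 <- y
    flips <- integer(0)
    for (grp in c(0, 1)) {
      idx <- which(g == grp)
      target <- if (grp == 0) k_u else k_p
      cur <- sum(y2[idx])
      if (target > cur) {
        cand <- idx[y2[idx] == 0]
        f <- sample(cand, target - cur)
        y2[f] <- 1L; flips <- c(flips, f)
      } else if (target < cur) {
        cand <- idx[y2[idx] == 1]
        f <- sample(cand, cur - target)
        y2[f] <- 0L; flips <- c(flips, f)
      }
    }
    df <- as.data.frame(ch)
    df[[cols_by_role(ch, "label")]] <- y2
    out <- rebuild(ch, df)
    append_log(out, "plant_outcome_bias", list(
      attribute = spec$attribute, bias_strength = bias_strength, seed = seed,
      flipped_rows = flips,
      achieved_gap = mean(y2[g == 0]) - mean(y2[g == 1]),
      positives_before = P, positives_after = sum(y2)
    ))
  })
}

## feasible bias_strength interval given total positives and group sizes
p_p_range <- function(P, n_u, n_p) {
  N <- n_u + n_p
  ## p_p = (P - n_u*b)/N must be in [0,1]; p_u = p_p + b in [0,1]
  ## b in [max((P-N)/n_u? ...)]: derive numerically over b grid endpoints
  b_from_pp <- function(pp) (P - N * pp) / n_u
  b1 <- sort(c(b_from_pp(0), b_from_pp(1)))
  ## p_u = (P + n_p*b)/N in [0,1]  =>  b in [-P/n_p, (N-P)/n_p]
  b2 <- c(-P / n_p, (N - P) / n_p)
  list(lo = max(b1[1], b2[1], -1), hi = min(b1[2], b2[2], 1))
}
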