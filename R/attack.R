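## Adversarial data manipulations: stratified label-flipping poisoning of
## training labels, and injection of a binary leakage proxy correlated with
## a sensitive attribute. Poisoning touches training rows only; the leakage
## proxy is systemic (all partitions) and is deliberately retained in the
## model-facing feature view.

#' Attack configuration
#'
#' @param kind `"poison"` (stratified label flipping, training rows only) or
#'   `"leak"` (sensitive-proxy feature injection, all partitions).
#' @param poison_rate fraction of training labels flipped; main setting 0.05,
#'   sensitivity sweep `{0, 0.05, 0.10, 0.15, 0.20}`.
#' @param leak_alpha agreement probability between the proxy and the
#'   sensitive attribute, default 0.90 (the proxy flips to `1 - s` with
#'   probability `1 - leak_alpha`).
#' @param seed base seed, default 4765416.
#' @return class `attack_config`.
#' @export
attack_config <- function(kind = c("poison", "leak"), poison_rate = 0.05,
                          leak_alpha = 0.90, seed = 4765416L) {
  kind <- match.arg(kind)
  stopifnot(poison_rate >= 0, poison_rate <= 1,
            leak_alpha >= 0, leak_alpha <= 1)
  structure(list(kind = kind, poison_rate = poison_rate,
                 leak_alpha = leak_alpha, seed = as.integer(seed)),
            class = "attack_config")
}

#' Stratified label-flipping poisoning
#'
#' Flips `y <- 1 - y` for a fraction `poison_rate` of the supplied training
#' labels, chosen uniformly without replacement within each stratum
#' (class x sensitive group). Flip counts are apportioned across strata by
#' largest remainder so the global count equals `round(rate * n)` exactly.
#' Within a stratum, flipped rows are the prefix of a seeded permutation, so
#' for a fixed seed the flip sets are nested across increasing rates. A
#' stratum smaller than its apportioned count is capped at its size and the
#' shortfall is logged, never silently redistributed.
#'
#' @param labels binary 0/1 training labels (training rows only -- validation
#'   and test labels are never passed in and therefore remain untouched).
#' @param strata stratum id per row (e.g. `interaction(label, group)`).
#' @param cfg an [attack_config()] with `kind = "poison"`.
#' @return list: `labels` (poisoned), `log` (class `attack_log`: realized
#'   rate, per-stratum flip counts, class priors before/after, shortfall,
#'   flipped row indices, seed).
#' @export
poison_labels <- function(labels, strata, cfg) {
  if (cfg$kind != "poison") stopf("attack_config kind must be 'poison'")
  y <- as.integer(labels)
  stopifnot(length(strata) == length(y))
  strata <- as.character(strata)
  n <- length(y)
  total <- as.integer(round(cfg$poison_rate * n))
  sizes <- table(strata)
  alloc <- apportion(total, as.numeric(sizes))
  names(alloc) <- names(sizes)

  flips <- integer(0)
  shortfall <- 0L
  per_stratum <- stats::setNames(integer(length(sizes)), names(sizes))
  with_seed(cfg$seed, {
    for (st in names(sizes)) {
      rows <- which(strata == st)
      k <- min(alloc[[st]], length(rows))
      shortfall <- shortfall + (alloc[[st]] - k)
      ## prefix of a per-stratum permutation: always drawn, so a fixed seed
      ## yields nested flip sets across increasing rates
      perm <- sample(rows)
      if (k > 0) {
        flips <- c(flips, perm[seq_len(k)])
        per_stratum[st] <- k
      }
    }
  })
  y2 <- y
  y2[flips] <- 1L - y2[flips]
  log <- structure(list(
    kind = "poison", rate = cfg$poison_rate,
    realized_rate = length(flips) / n,
    n = n, total_flips = length(flips),
    flips_per_stratum = as.list(per_stratum),
    shortfall = shortfall,
    priors_before = as.list(prop.table(table(factor(y, levels = 0:1)))),
    priors_after = as.list(prop.table(table(factor(y2, levels = 0:1)))),
    flipped_rows = sort(flips),
    seed = cfg$seed
  ), class = "attack_log")
  list(labels = y2, log = log)
}

#' Inject a sensitive-attribute leakage proxy feature
#'
#' Adds a binary column `leak_s` agreeing with the sensitive attribute `s`
#' with probability `leak_alpha`, independently per row, across *all*
#' partitions (systemic leakage). On a cohort, the column is tagged with role
#' `leak` so the feature-exclusion policy retains it in the model-facing
#' view.
#'
#' @param x a cohort, or a data.frame of feature rows.
#' @param s binary sensitive vector aligned with the rows of `x`.
#' @param cfg an [attack_config()] with `kind = "leak"`.
#' @return list: `data` (cohort or data.frame with `leak_s` appended), `log`
#'   (class `attack_log`: empirical agreement, seed).
#' @export
inject_leak_feature <- function(x, s, cfg) {
  if (cfg$kind != "leak") stopf("attack_config kind must be 'leak'")
  s <- as.integer(s)
  stopifnot(is_binary01(s), length(s) == nrow(x))
  leak <- with_seed(cfg$seed, {
    agree <- stats::runif(length(s)) < cfg$leak_alpha
    ifelse(agree, s, 1L - s)
  })
  log <- structure(list(
    kind = "leak", alpha = cfg$leak_alpha,
    empirical_agreement = mean(leak == s),
    n = length(s), seed = cfg$seed
  ), class = "attack_log")
  if (inherits(x, "cohort")) {
    df <- as.data.frame(x)
    df$leak_s <- as.integer(leak)
    rl <- roles(x); rl["leak_s"] <- "leak"
    out <- rebuild(x, df, roles_new = rl)
    out <- append_log(out, "inject_leak_feature", log)
  } else {
    out <- as.data.frame(x)
    out$leak_s <- as.integer(leak)
  }
  list(data = out, log = log)
}

#' Serialize an attack log to JSON
#' @param log an `attack_log`.
#' @param path output path.
#' @export
write_attack_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
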