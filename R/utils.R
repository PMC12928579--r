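`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a run-specific seed from a base seed
#'
#' Deterministic scheme `base + fold + 1000 * repeat`, kept below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param base base seed (integer).
#' @param fold fold index (0-based contribution), default 0.
#' @param rep repeat index (0-based contribution), default 0.
#' @return an integer seed.
#' @export
derive_seed <- function(base, fold = 0, rep = 0) {
  s <- (as.double(base) + fold + 1000 * rep) %% 2147483647
  as.integer(s)
}

## run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so package functions never clobber user state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## largest-remainder apportionment of `total` into parts proportional to `weights`
apportion <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) == 0 || all(x %in% c(0, 1))
}
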