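#' Cohort container
#'
#' A cohort is a `data.frame` carrying one row per participant plus a named
#' `roles` attribute tagging every column with one of:
#' \describe{
#'   \item{`clinical`}{numeric clinical feature, eligible for model training.}
#'   \item{`sensitive`}{raw sensitive attribute (age, gender, race); audited,
#'     never used as a training feature.}
#'   \item{`sensitive_bin`}{derived binary group column (1 = privileged).}
#'   \item{`label`}{the binary diagnosis label (1 = case).}
#'   \item{`leak`}{an injected leakage proxy column; by design it *does*
#'     enter the model-facing feature view.}
#' }
#' An `audit_log` attribute accumulates per-stage processing logs.
#'
#' @param data a `data.frame`.
#' @param roles named character vector, one role per column of `data`.
#' @return an object of class `cohort`.
#' @export
cohort <- function(data, roles) {
  stopifnot(is.data.frame(data))
  if (is.null(names(roles)) || !setequal(names(roles), names(data)))
    stopf("roles must be a named vector covering exactly the columns of data")
  bad <- setdiff(unique(roles), c("clinical", "sensitive", "sensitive_bin", "label", "leak"))
  if (length(bad)) stopf("unknown role(s): %s", paste(bad, collapse = ", "))
  if (sum(roles == "label") != 1) stopf("exactly one column must have role 'label'")
  lab <- data[[names(roles)[roles == "label"]]]
  if (!is_binary01(lab)) stopf("label column must be binary 0/1")
  ## sensitive columns must never be tagged clinical (enforced by construction:
  ## roles is a function, one role per column)
  structure(
    as.data.frame(data),
    roles = roles[names(data)],
    audit_log = attr(data, "audit_log") %||% list(),
    class = c("cohort", "data.frame")
  )
}

#' @export
roles <- function(ch) attr(ch, "roles")

#' @export
cohort_log <- function(ch) attr(ch, "audit_log")

append_log <- function(ch, stage, entry) {
  lg <- attr(ch, "audit_log") %||% list()
  lg[[length(lg) + 1]] <- c(list(stage = stage), entry)
  attr(ch, "audit_log") <- lg
  ch
}

## rebuild a cohort after row/column surgery, preserving attributes
rebuild <- function(ch, data, roles_new = NULL) {
  out <- cohort(data, (roles_new %||% roles(ch))[names(data)])
  attr(out, "audit_log") <- attr(ch, "audit_log")
  out
}

cols_by_role <- function(ch, role) names(roles(ch))[roles(ch) %in% role]

#' Extract the binary label vector (1 = case)
#' @param ch a cohort.
#' @export
cohort_label <- function(ch) as.integer(ch[[cols_by_role(ch, "label")]])

#' Sensitive-attribute audit view (raw + binarized columns)
#' @param ch a cohort.
#' @export
cohort_sensitive <- function(ch) {
  as.data.frame(ch)[, cols_by_role(ch, c("sensitive", "sensitive_bin")), drop = FALSE]
}

#' Model-facing feature view
#'
#' Returns the columns a model may see: clinical features plus any injected
#' leakage column. Sensitive attributes (raw and binarized) and the label are
#' excluded. This is the feature-exclusion policy applied before training.
#'
#' @param ch a cohort.
#' @return a `data.frame` of model-facing features.
#' @export
exclude_sensitive_from_features <- function(ch) {
  as.data.frame(ch)[, cols_by_role(ch, c("clinical", "leak")), drop = FALSE]
}

#' @rdname exclude_sensitive_from_features
#' @export
cohort_features <- exclude_sensitive_from_features

keep_rows <- function(ch, idx) rebuild(ch, as.data.frame(ch)[idx, , drop = FALSE])

#' @export
print.cohort <- function(x, ...) {
  rl <- roles(x)
  cat(sprintf(
    "<cohort> %d participants, %d columns (%d clinical, %d sensitive, %d leak)\n",
    nrow(x), ncol(x), sum(rl == "clinical"),
    sum(rl %in% c("sensitive", "sensitive_bin")), sum(rl == "leak")
  ))
  lab <- cohort_label(x)
  cat(sprintf("  label: %d positive / %d negative\n", sum(lab == 1), sum(lab == 0)))
  invisible(x)
}

#' Write a cohort as CSV plus a JSON sidecar schema
#'
#' The sidecar records column roles and types and an echo of arbitrary
#' metadata (e.g. the generating config and seed) so the pair round-trips
#' losslessly through [read_cohort()].
#'
#' @param ch a cohort.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @param meta optional list echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ch, path, meta = NULL) {
  utils::write.csv(as.data.frame(ch), path, row.names = FALSE)
  schema <- list(
    columns = names(ch),
    roles = as.list(roles(ch)),
    types = as.list(vapply(as.data.frame(ch), function(c) class(c)[1], "")),
    meta = meta
  )
  jsonlite::write_json(schema, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path CSV path written by [write_cohort()].
#' @return a cohort.
#' @export
read_cohort <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    tp <- schema$types[[nm]]
    if (!is.null(tp)) {
      df[[nm]] <- switch(tp,
        integer = as.integer(df[[nm]]),
        numeric = as.numeric(df[[nm]]),
        character = as.character(df[[nm]]),
        df[[nm]]
      )
    }
  }
  cohort(df, unlist(schema$roles)[names(df)])
}
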