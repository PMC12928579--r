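#' Define a sensitive attribute and its binarization rule
#'
#' A sensitive spec maps a raw sensitive column onto two bins and designates
#' one bin as privileged. Three rule types cover the cohort's attributes:
#' \describe{
#'   \item{`threshold`}{numeric attribute split at `cut`: bins `"<cut"` and
#'     `">=cut"` (used for age; default cut 60 years).}
#'   \item{`category`}{categorical attribute split into `privileged` vs
#'     everything else (used for race: White vs Non-White).}
#'   \item{`binary`}{attribute already coded 0/1; `privileged` names the
#'     privileged code (used for gender, 1 = male).}
#' }
#'
#' @param attribute column name of the raw sensitive attribute.
#' @param type rule type, one of `"threshold"`, `"category"`, `"binary"`.
#' @param privileged the privileged bin: for `threshold` one of `"<cut"` /
#'   `">=cut"`; for `category` the privileged level; for `binary` 0 or 1.
#' @param cut cut point in the attribute's units (threshold rule only).
#' @return an object of class `sensitive_spec`.
#' @export
#' @examples
#' sensitive_spec("age", "threshold", privileged = "<cut", cut = 60)
#' sensitive_spec("race", "category", privileged = "White")
sensitive_spec <- function(attribute, type = c("threshold", "category", "binary"),
                           privileged, cut = NULL) {
  type <- match.arg(type)
  if (type == "threshold") {
    stopifnot(is.numeric(cut), length(cut) == 1)
    if (!privileged %in% c("<cut", ">=cut"))
      stopf("threshold rule: privileged must be \"<cut\" or \">=cut\"")
  }
  if (type == "binary" && !privileged %in% c(0, 1))
    stopf("binary rule: privileged must be 0 or 1")
  structure(list(attribute = attribute, type = type,
                 privileged = privileged, cut = cut),
            class = "sensitive_spec")
}

#' Default sensitive specs: age (<60 privileged), race (White), gender (male)
#'
#' Privileged designations follow the cohort's majority/overrepresentation
#' structure (older, White, male participants dominate the case group) so that
#' disparities against the minority bins carry a consistent sign. All three
#' are plain [sensitive_spec()] objects and fully configurable.
#'
#' @return named list of `sensitive_spec`s for `age`, `race`, `gender`.
#' @export
default_sensitive_specs <- function() {
  list(
    age    = sensitive_spec("age", "threshold", privileged = "<cut", cut = 60),
    race   = sensitive_spec("race", "category", privileged = "White"),
    gender = sensitive_spec("gender", "binary", privileged = 1)
  )
}

#' Apply a sensitive spec, returning the binary group vector (1 = privileged)
#'
#' The rule is total: every non-missing raw value maps to exactly one bin;
#' an unmapped (missing) raw value is an error listing the offending rows.
#'
#' @param ch a cohort (or data.frame containing the raw attribute column).
#' @param spec a [sensitive_spec()].
#' @return integer vector, 1 = privileged, 0 = unprivileged.
#' @export
group_vector <- function(ch, spec) {
  x <- ch[[spec$attribute]]
  if (is.null(x)) stopf("sensitive attribute '%s' not found", spec$attribute)
  if (anyNA(x))
    stopf("sensitive attribute '%s' has unmapped (missing) values in rows: %s",
          spec$attribute, paste(utils::head(which(is.na(x)), 10), collapse = ", "))
  g <- switch(spec$type,
    threshold = if (spec$privileged == "<cut") x < spec$cut else x >= spec$cut,
    category  = x == spec$privileged,
    binary    = x == spec$privileged
  )
  as.integer(g)
}
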