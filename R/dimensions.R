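#' Define an equity stratifier (inequality dimension)
#'
#' A dimension describes one population grouping variable along which a
#' coverage indicator is disaggregated: its measurement kind, the ordering of
#' its subgroups, the fixed high/low convention used by the pairwise
#' difference and ratio, and the rule that picks the reference subgroup for
#' the population attributable risk (PAR).
#'
#' @param name Column name in the record/estimate data.
#' @param kind `"ordered"` (inherent advantage ordering, e.g. wealth
#'   quintiles), `"binary"`, or `"non_ordered"` (e.g. subnational region).
#'   The slope and relative indices of inequality (SII/RII) are only
#'   applicable to ordered dimensions with at least three subgroups.
#' @param subgroups Character vector of subgroup labels. For ordered
#'   dimensions the order runs from most disadvantaged to most advantaged.
#'   May be `NULL` for non-ordered dimensions whose levels come from data.
#' @param reference_rule How PAR picks its reference subgroup:
#'   `"most_advantaged"` (last element of `subgroups`), `"best_performing"`
#'   (subgroup with the highest estimate, the convention for non-ordered
#'   dimensions), or `"fixed:<label>"`.
#' @param high_subgroup,low_subgroup Fixed labels used as the minuend /
#'   subtrahend of the difference (and numerator / denominator of the
#'   ratio). Required for binary dimensions; ignored for ordered dimensions
#'   (extremes of the ordering are used) and for non-ordered dimensions
#'   (best and worst performing subgroups are used).
#'
#' @return An object of class `equicov_dimension`.
#' @examples
#' dimension_spec("wealth_quintile", "ordered",
#'                c("Q1", "Q2", "Q3", "Q4", "Q5"))
#' @export
dimension_spec <- function(name,
                           kind = c("ordered", "binary", "non_ordered"),
                           subgroups = NULL,
                           reference_rule = NULL,
                           high_subgroup = NULL,
                           low_subgroup = NULL) {
  kind <- match.arg(kind)
  if (kind == "ordered") {
    if (is.null(subgroups) || length(subgroups) < 3) {
      abort("ordered dimensions need >= 3 ordered subgroups (else declare them binary)")
    }
  }
  if (kind == "binary") {
    if (is.null(subgroups) || length(subgroups) != 2) {
      abort("binary dimensions need exactly 2 subgroups")
    }
    if (is.null(high_subgroup) || is.null(low_subgroup)) {
      abort("binary dimensions need an explicit high/low convention")
    }
    stopifnot(high_subgroup %in% subgroups, low_subgroup %in% subgroups)
  }
  if (is.null(reference_rule)) {
    reference_rule <- switch(kind,
      ordered = "most_advantaged",
      binary = paste0("fixed:", high_subgroup),
      non_ordered = "best_performing"
    )
  }
  ok <- reference_rule %in% c("most_advantaged", "best_performing") ||
    startsWith(reference_rule, "fixed:")
  if (!ok) abort("unknown reference_rule: ", reference_rule)
  structure(
    list(
      name = name, kind = kind, subgroups = subgroups,
      reference_rule = reference_rule,
      high_subgroup = high_subgroup, low_subgroup = low_subgroup
    ),
    class = "equicov_dimension"
  )
}

#' @export
print.equicov_dimension <- function(x, ...) {
  cat("<equicov_dimension> ", x$name, " [", x$kind, "]\n", sep = "")
  if (!is.null(x$subgroups)) {
    cat("  subgroups: ", paste(x$subgroups, collapse = " < "), "\n", sep = "")
  }
  cat("  reference: ", x$reference_rule, "\n", sep = "")
  invisible(x)
}

#' Default equity stratifiers for a DHS-type child immunization analysis
#'
#' The five standard dimensions: household wealth quintile and maternal
#' education (ordered), place of residence and child sex (binary, with the
#' fixed conventions urban - rural and female - male), and subnational
#' region (non-ordered, reference = best-performing region).
#'
#' @param regions Optional character vector of region labels (taken from the
#'   data when `NULL`).
#' @return Named list of [dimension_spec()] objects.
#' @export
default_dimensions <- function(regions = NULL) {
  list(
    wealth_quintile = dimension_spec(
      "wealth_quintile", "ordered", c("Q1", "Q2", "Q3", "Q4", "Q5")
    ),
    maternal_education = dimension_spec(
      "maternal_education", "ordered", c("none", "primary", "secondary+")
    ),
    residence = dimension_spec(
      "residence", "binary", c("rural", "urban"),
      high_subgroup = "urban", low_subgroup = "rural"
    ),
    sex = dimension_spec(
      "sex", "binary", c("female", "male"),
      high_subgroup = "female", low_subgroup = "male"
    ),
    region = dimension_spec(
      "region", "non_ordered", regions,
      reference_rule = "best_performing"
    )
  )
}

# Resolve the PAR reference subgroup for a set of estimates (one dimension-year)
resolve_reference <- function(spec, estimates) {
  rule <- spec$reference_rule
  if (startsWith(rule, "fixed:")) {
    ref <- sub("^fixed:", "", rule)
  } else if (rule == "most_advantaged") {
    sg <- spec$subgroups %||% unique(estimates$subgroup)
    ref <- sg[length(sg)]
  } else { # best_performing
    ref <- estimates$subgroup[which.max(estimates$estimate)]
  }
  if (!ref %in% estimates$subgroup) {
    abort(paste0("reference subgroup '", ref, "' has no estimate"))
  }
  ref
}
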