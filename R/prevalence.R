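# Design-based mean of a binary indicator.
#
# Point estimate: ratio estimator sum(w*y)/sum(w). Variance: Taylor
# linearization under the with-replacement PSU approximation, stratified by
# region when a strata column is present:
#   u_c   = sum_{i in PSU c} w_i (y_i - p)
#   var_h = m_h/(m_h - 1) * sum_c (u_hc - mean_h)^2
#   var(p) = sum_h var_h / (sum w)^2
# CI on the logit scale (back-transformed), which respects [0, 1]; degenerate
# all-0 / all-1 groups fall back to a one-sided Clopper-Pearson interval on
# the Kish effective sample size.
svy_mean <- function(y, w, cluster, strata = NULL) {
  tot <- sum(w)
  p <- sum(w * y) / tot
  n_eff <- tot^2 / sum(w^2)
  if (is.null(strata)) strata <- rep(1L, length(y))
  u <- tapply(w * (y - p), list(strata, cluster), sum)
  v <- 0
  for (h in rownames(u)) {
    uh <- u[h, ]
    uh <- uh[!is.na(uh)]
    mh <- length(uh)
    if (mh > 1) v <- v + mh / (mh - 1) * sum((uh - mean(uh))^2)
    # single-PSU stratum contributes no variance (certainty approximation)
  }
  se <- sqrt(v) / tot
  z <- qnorm(0.975)
  if (p <= 0 || p >= 1 || se == 0) {
    if (p <= 0) {
      ci <- c(0, 1 - (0.05)^(1 / max(n_eff, 1)))        # one-sided exact
    } else if (p >= 1) {
      ci <- c((0.05)^(1 / max(n_eff, 1)), 1)
    } else {
      ci <- c(p, p)
    }
  } else {
    l <- qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- plogis(c(l - z * se_l, l + z * se_l))
  }
  list(p = p, se = se, ci_low = ci[1], ci_high = ci[2],
       n_eff = n_eff, w_total = tot, n = length(y))
}

#' Survey-weighted prevalence of the indicator
#'
#' Computes the weighted national (setting) average, or one weighted
#' estimate per subgroup of a dimension, with design-based 95% confidence
#' intervals (Taylor linearization over PSUs within region strata,
#' logit-scale Wald interval) and population shares.
#'
#' @param records Child-record tibble with at least `outcome`,
#'   `sampling_weight`, `cluster_id` and `survey_year` (and `region` for
#'   stratified variance).
#' @param by Optional [dimension_spec()]: when supplied, one estimate per
#'   subgroup is returned (the Table-2-style surface); when `NULL`, the
#'   national average per year.
#' @return A tibble: per year `estimate` (percent), `ci_low`, `ci_high`,
#'   `se`, `n_effective`, and additionally `dimension`, `subgroup`,
#'   `population_share` when `by` is given. Subgroups with
#'   `n_effective < 25` are flagged in a `low_n` column, not suppressed.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' rec <- generate_population(cfg, 2019)
#' weighted_prevalence(rec)
#' @export
weighted_prevalence <- function(records, by = NULL) {
  if (nrow(records) == 0) abort("no records")
  if (any(records$sampling_weight <= 0)) abort("weights must be positive")
  strata_col <- if ("region" %in% names(records)) records$region else NULL

  per_year <- function(rec) {
    strat <- if (!is.null(strata_col)) rec$region else NULL
    if (is.null(by)) {
      m <- svy_mean(rec$outcome, rec$sampling_weight, rec$cluster_id, strat)
      return(tibble::tibble(
        year = rec$survey_year[1],
        estimate = 100 * m$p, ci_low = 100 * m$ci_low,
        ci_high = 100 * m$ci_high, se = 100 * m$se,
        n_effective = m$n_eff
      ))
    }
    g <- rec[[by$name]]
    if (is.null(g)) abort(paste0("records lack column '", by$name, "'"))
    keep <- !is.na(g)
    rec <- rec[keep, ]
    g <- g[keep]
    levels_here <- by$subgroups %||% sort(unique(g))
    unknown <- setdiff(unique(g), levels_here)
    if (length(unknown)) {
      abort(paste0("unknown subgroup label(s) in '", by$name, "': ",
                   paste(unknown, collapse = ", ")))
    }
    tot_w <- sum(rec$sampling_weight)
    rows <- lapply(levels_here, function(sg) {
      idx <- g == sg
      if (!any(idx)) {
        warn(paste0("subgroup '", sg, "' has zero weight; dropped"))
        return(NULL)
      }
      sub <- rec[idx, ]
      strat <- if (!is.null(strata_col)) sub$region else NULL
      m <- svy_mean(sub$outcome, sub$sampling_weight, sub$cluster_id, strat)
      tibble::tibble(
        dimension = by$name, subgroup = sg, year = sub$survey_year[1],
        estimate = 100 * m$p, ci_low = 100 * m$ci_low,
        ci_high = 100 * m$ci_high, se = 100 * m$se,
        population_share = m$w_total / tot_w,
        n_effective = m$n_eff, low_n = m$n_eff < 25
      )
    })
    dplyr::bind_rows(rows)
  }

  out <- records |>
    dplyr::group_split(.data$survey_year) |>
    purrr::map_dfr(per_year)
  out
}

#' Disaggregate the indicator by several equity stratifiers
#'
#' One weighted subgroup estimate per (dimension, subgroup, survey year) —
#' the long form of the classic disaggregated-coverage table.
#'
#' @param records Child-record tibble.
#' @param dimensions List of [dimension_spec()] objects (default:
#'   [default_dimensions()] restricted to columns present in the data).
#' @param years Optional subset of survey years.
#' @return Tibble of subgroup estimates; population shares sum to 1 within
#'   each dimension-year.
#' @export
disaggregate <- function(records, dimensions = NULL, years = NULL) {
  if (!is.null(years)) records <- records[records$survey_year %in% years, ]
  if (nrow(records) == 0) abort("no records for requested years")
  if (is.null(dimensions)) {
    dimensions <- default_dimensions(regions = sort(unique(records$region)))
    dimensions <- dimensions[vapply(dimensions, function(d) {
      d$name %in% names(records)
    }, logical(1))]
  }
  purrr::map_dfr(dimensions, function(d) weighted_prevalence(records, by = d))
}
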