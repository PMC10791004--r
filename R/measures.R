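# Standard errors for table-fed estimates are back-derived from the reported
# 95% interval half-width; record-level inputs carry their design-based SE.
se_from_table <- function(est) {
  if ("se" %in% names(est) && all(is.finite(est[["se"]]))) return(est[["se"]])
  (est$ci_high - est$ci_low) / (2 * qnorm(0.975))
}

measure_row <- function(measure, dimension, year, value, se = NA_real_,
                        ci = c(NA_real_, NA_real_), null_value = 0,
                        reference_subgroup = NA_character_,
                        applicable = TRUE, value_raw = value) {
  classes <- list(
    D = c("absolute", "simple"), R = c("relative", "simple"),
    SII = c("absolute", "complex"), RII = c("relative", "complex"),
    PAR = c("absolute", "complex"), PAF = c("relative", "complex")
  )[[measure]]
  significant <- if (applicable && all(is.finite(ci))) {
    ci[1] > null_value || ci[2] < null_value
  } else {
    NA
  }
  tibble::new_tibble(list(
    dimension = dimension, measure = measure, year = year,
    value = if (applicable) value else NA_real_,
    value_raw = if (applicable) value_raw else NA_real_,
    se = se, ci_low = ci[1], ci_high = ci[2],
    measure_type = classes[1], measure_complexity = classes[2],
    null_value = null_value, significant = significant,
    reference_subgroup = reference_subgroup, applicable = applicable
  ), nrow = 1L)
}

# High/low subgroup selection conventions: ordered = extremes of the stated
# ordering; binary = the spec's fixed convention (female - male, urban -
# rural); non-ordered = best minus worst performing.
high_low <- function(est, spec) {
  if (spec$kind == "binary") {
    hi <- spec$high_subgroup
    lo <- spec$low_subgroup
  } else if (spec$kind == "ordered") {
    sg <- intersect(spec$subgroups, est$subgroup)
    hi <- sg[length(sg)]
    lo <- sg[1]
  } else {
    hi <- est$subgroup[which.max(est$estimate)]
    lo <- est$subgroup[which.min(est$estimate)]
  }
  if (!all(c(hi, lo) %in% est$subgroup)) {
    abort(paste0("missing required subgroup for dimension '", spec$name, "'"))
  }
  list(
    hi = hi, lo = lo,
    y_hi = est$estimate[est$subgroup == hi][1],
    y_lo = est$estimate[est$subgroup == lo][1],
    se_hi = se_from_table(est)[est$subgroup == hi][1],
    se_lo = se_from_table(est)[est$subgroup == lo][1]
  )
}

one_dimension_year <- function(est, spec) {
  if (length(unique(est$year)) != 1) abort("estimates span several years")
  if (nrow(est) < 2) abort("need at least 2 subgroup estimates")
  est
}

#' Difference between the most and least advantaged subgroups (D)
#'
#' Simple absolute inequality: `D = y_high - y_low` in percentage points.
#' Inequality is declared when the 95% CI excludes 0.
#'
#' @param estimates Subgroup-estimate tibble for one dimension and year
#'   (columns `subgroup`, `estimate`, `ci_low`, `ci_high`,
#'   `population_share`).
#' @param spec The [dimension_spec()] of the dimension.
#' @return One-row measure tibble.
#' @export
inequality_difference <- function(estimates, spec) {
  est <- one_dimension_year(estimates, spec)
  hl <- high_low(est, spec)
  d <- hl$y_hi - hl$y_lo
  se <- sqrt(hl$se_hi^2 + hl$se_lo^2)
  z <- qnorm(0.975)
  measure_row("D", spec$name, est$year[1], d, se,
              ci = c(d - z * se, d + z * se), null_value = 0)
}

#' Ratio of the most to the least advantaged subgroup (R)
#'
#' Simple relative inequality: `R = y_high / y_low`. The CI is delta-method
#' on the log scale; inequality is declared when the CI excludes 1.
#'
#' @inheritParams inequality_difference
#' @return One-row measure tibble.
#' @export
inequality_ratio <- function(estimates, spec) {
  est <- one_dimension_year(estimates, spec)
  hl <- high_low(est, spec)
  if (hl$y_lo <= 0) {
    return(measure_row("R", spec$name, est$year[1], NA_real_,
                       null_value = 1, applicable = FALSE))
  }
  r <- hl$y_hi / hl$y_lo
  se_log <- sqrt((hl$se_hi / hl$y_hi)^2 + (hl$se_lo / hl$y_lo)^2)
  z <- qnorm(0.975)
  measure_row("R", spec$name, est$year[1], r, r * se_log,
              ci = r * exp(c(-z, z) * se_log), null_value = 1)
}

# Ridit midpoints and the WLS line through (midpoint, estimate) with
# population-share weights. Returns the fitted values at rank 0 and rank 1
# and, for delta-method CIs, the rows of the linear map y -> (v0, v1).
ridit_line <- function(est, spec, scale = c("linear", "logit")) {
  scale <- match.arg(scale)
  sg <- intersect(spec$subgroups, est$subgroup)
  est <- est[match(sg, est$subgroup), ]
  sh <- est$population_share
  if (abs(sum(sh) - 1) > 0.05) abort("population shares do not sum to ~1")
  sh <- sh / sum(sh)
  x <- cumsum(sh) - sh / 2                    # ridit midpoints
  y <- est$estimate
  if (scale == "logit") {
    p <- pmin(pmax(y / 100, 1e-6), 1 - 1e-6)
    y <- qlogis(p)
  }
  X <- cbind(1, x)
  W <- diag(sh, nrow = length(sh))
  L <- solve(t(X) %*% W %*% X, t(X) %*% W)    # beta = L y
  A <- rbind(c(1, 0), c(1, 1))                # (v0, v1) = A beta
  M <- A %*% L
  v <- drop(M %*% y)
  se_y <- se_from_table(est)
  if (scale == "logit") se_y <- se_y / 100 / (plogis(y) * (1 - plogis(y)))
  Sigma <- M %*% diag(se_y^2, nrow = length(se_y)) %*% t(M)
  if (scale == "logit") {
    g <- 100 * plogis(v) * (1 - plogis(v))    # d/dv of 100*plogis
    Sigma <- diag(g) %*% Sigma %*% diag(g)
    v <- 100 * plogis(v)
  }
  list(v0 = v[1], v1 = v[2], cov = Sigma, subgroups = sg)
}

#' Slope index of inequality (SII)
#'
#' Regression-based absolute inequality over the full ordered distribution:
#' subgroups are placed at the midpoints of their cumulative
#' population-share intervals (ridits) and a weighted least-squares line of
#' the estimate on the midpoint (weights = population shares) is fitted;
#' `SII = v1 - v0`, the fitted values at rank 1 and rank 0. Only applicable
#' to ordered dimensions with at least three subgroups — for binary or
#' non-ordered dimensions an inapplicable (`NA`) row is returned.
#'
#' @inheritParams inequality_difference
#' @param scale `"linear"` (default) fits the percentage directly;
#'   `"logit"` fits on the log-odds scale and back-transforms the rank-0/1
#'   endpoints.
#' @return One-row measure tibble.
#' @export
slope_index <- function(estimates, spec, scale = c("linear", "logit")) {
  est <- one_dimension_year(estimates, spec)
  if (spec$kind != "ordered" || length(spec$subgroups) < 3) {
    return(measure_row("SII", spec$name, est$year[1], NA_real_,
                       applicable = FALSE))
  }
  fit <- ridit_line(est, spec, scale)
  sii <- fit$v1 - fit$v0
  se <- sqrt(fit$cov[1, 1] + fit$cov[2, 2] - 2 * fit$cov[1, 2])
  z <- qnorm(0.975)
  measure_row("SII", spec$name, est$year[1], sii, se,
              ci = c(sii - z * se, sii + z * se), null_value = 0)
}

#' Relative index of inequality (RII)
#'
#' `RII = v1 / v0` from the same ridit regression line as [slope_index()];
#' the CI is delta-method on the log scale and inequality is declared when
#' it excludes 1. Inapplicable to binary and non-ordered dimensions.
#'
#' @inheritParams slope_index
#' @return One-row measure tibble.
#' @export
relative_index <- function(estimates, spec, scale = c("linear", "logit")) {
  est <- one_dimension_year(estimates, spec)
  if (spec$kind != "ordered" || length(spec$subgroups) < 3) {
    return(measure_row("RII", spec$name, est$year[1], NA_real_,
                       null_value = 1, applicable = FALSE))
  }
  fit <- ridit_line(est, spec, scale)
  if (fit$v0 <= 0) {
    warn("fitted line crosses zero at rank 0; RII undefined")
    return(measure_row("RII", spec$name, est$year[1], NA_real_,
                       null_value = 1, applicable = FALSE))
  }
  rii <- fit$v1 / fit$v0
  g <- c(-1 / fit$v0, 1 / fit$v1)             # gradient of log(v1/v0)
  se_log <- sqrt(drop(t(g) %*% fit$cov %*% g))
  z <- qnorm(0.975)
  measure_row("RII", spec$name, est$year[1], rii, rii * se_log,
              ci = rii * exp(c(-z, z) * se_log), null_value = 1)
}

#' Population attributable risk (PAR)
#'
#' Absolute improvement in the setting (national) average achievable if
#' every subgroup had the reference subgroup's coverage:
#' `PAR = y_ref - mu`. For a favorable indicator the value is floored at 0
#' when the reference sits at or below the national average; the raw
#' (un-floored) value is kept in `value_raw` and drives the CI.
#'
#' @inheritParams inequality_difference
#' @param national One-row national-average tibble for the same year
#'   (columns `year`, `estimate`, and optionally `se` / CI bounds).
#' @return One-row measure tibble.
#' @export
attributable_risk <- function(estimates, spec, national) {
  est <- one_dimension_year(estimates, spec)
  nat <- national[national$year == est$year[1], ]
  if (nrow(nat) != 1) abort("no (unique) national average for this year")
  ref <- resolve_reference(spec, est)
  y_ref <- est$estimate[est$subgroup == ref][1]
  raw <- y_ref - nat$estimate
  se_ref <- se_from_table(est)[est$subgroup == ref][1]
  se_mu <- if ("se" %in% names(nat) && is.finite(nat[["se"]])) {
    nat[["se"]]
  } else if (all(c("ci_low", "ci_high") %in% names(nat)) &&
             all(is.finite(c(nat$ci_low, nat$ci_high)))) {
    (nat$ci_high - nat$ci_low) / (2 * qnorm(0.975))
  } else {
    NA_real_
  }
  se <- sqrt(se_ref^2 + se_mu^2)
  z <- qnorm(0.975)
  ci <- if (is.finite(se)) c(raw - z * se, raw + z * se) else c(NA_real_, NA_real_)
  measure_row("PAR", spec$name, est$year[1], max(0, raw), se, ci,
              null_value = 0, reference_subgroup = ref, value_raw = raw)
}

#' Population attributable fraction (PAF)
#'
#' Relative counterpart of [attributable_risk()]:
#' `PAF = 100 * PAR / mu`, computed from the un-rounded internal values.
#'
#' @param par One-row PAR result from [attributable_risk()].
#' @param national One-row national-average tibble for the same year.
#' @return One-row measure tibble.
#' @export
attributable_fraction <- function(par, national) {
  nat <- national[national$year == par$year[1], ]
  if (nrow(nat) != 1) abort("no (unique) national average for this year")
  mu <- nat$estimate
  if (mu <= 0) abort("national average must be positive for PAF")
  paf <- 100 * par$value / mu
  se <- 100 * par$se / mu
  z <- qnorm(0.975)
  raw <- 100 * par$value_raw / mu
  ci <- if (is.finite(se)) c(raw - z * se, raw + z * se) else c(NA_real_, NA_real_)
  measure_row("PAF", par$dimension[1], par$year[1], paf, se, ci,
              null_value = 0, reference_subgroup = par$reference_subgroup[1],
              value_raw = raw)
}

ALL_MEASURES <- c("D", "R", "SII", "RII", "PAR", "PAF")

compute_measures_one <- function(est, spec, nat, measures, sii_scale) {
  out <- list()
  if ("D" %in% measures) out$D <- inequality_difference(est, spec)
  if ("R" %in% measures) out$R <- inequality_ratio(est, spec)
  if ("SII" %in% measures) out$SII <- slope_index(est, spec, sii_scale)
  if ("RII" %in% measures) out$RII <- relative_index(est, spec, sii_scale)
  if (any(c("PAR", "PAF") %in% measures)) {
    par <- attributable_risk(est, spec, nat)
    if ("PAR" %in% measures) out$PAR <- par
    if ("PAF" %in% measures) out$PAF <- attributable_fraction(par, nat)
  }
  dplyr::bind_rows(out)
}

#' Compute the six summary measures of inequality
#'
#' For every dimension-year, computes the difference (D), ratio (R), slope
#' and relative indices of inequality (SII/RII — ordered dimensions only),
#' and population attributable risk and fraction (PAR/PAF), each with a 95%
#' CI and a significance verdict (CI excludes 0 for absolute measures, 1
#' for ratios).
#'
#' Two input modes:
#' * an estimate table (`estimates` + `national`), e.g. published
#'   disaggregated coverage — CIs by the delta method from the reported
#'   interval widths;
#' * record-level data (`records`) — estimates are computed internally and
#'   CIs by a stratified cluster bootstrap (PSUs resampled with replacement
#'   within region strata, `boot_B` replicates).
#'
#' @param estimates Subgroup-estimate tibble (long, as from
#'   [disaggregate()] or [read_estimates_csv()]).
#' @param national National-average tibble (`year`, `estimate`, optional CI).
#' @param dimensions List of [dimension_spec()]s; defaults to
#'   [default_dimensions()] for the dimensions present.
#' @param measures Subset of `c("D","R","SII","RII","PAR","PAF")`.
#' @param records Optional child-record tibble; overrides
#'   `estimates`/`national`.
#' @param boot_B Bootstrap replicates for record-level CIs (0 = delta CIs).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param sii_scale Scale of the ridit regression, see [slope_index()].
#' @return Long measure tibble, one row per dimension-measure-year.
#' @export
summary_measures <- function(estimates = NULL, national = NULL,
                             dimensions = NULL,
                             measures = ALL_MEASURES,
                             records = NULL,
                             boot_B = 1000, boot_seed = 1L,
                             sii_scale = c("linear", "logit")) {
  sii_scale <- match.arg(sii_scale)
  measures <- match.arg(measures, ALL_MEASURES, several.ok = TRUE)
  if (!is.null(records)) {
    if (is.null(dimensions)) {
      dimensions <- default_dimensions(regions = sort(unique(records$region)))
      dimensions <- dimensions[vapply(dimensions, function(d)
        d$name %in% names(records), logical(1))]
    }
    estimates <- disaggregate(records, dimensions)
    national <- weighted_prevalence(records)
  }
  if (is.null(estimates) || is.null(national)) {
    abort("supply either an estimate table plus national averages, or records")
  }
  if (is.null(dimensions)) {
    dims_in <- unique(estimates$dimension)
    dimensions <- default_dimensions()
    dimensions <- dimensions[vapply(dimensions, function(d)
      d$name %in% dims_in, logical(1))]
    extra <- setdiff(dims_in, vapply(dimensions, `[[`, "", "name"))
    for (e in extra) {
      dimensions[[e]] <- dimension_spec(e, "non_ordered",
                                        reference_rule = "best_performing")
    }
  }

  point <- purrr::map_dfr(dimensions, function(spec) {
    est_d <- estimates[estimates$dimension == spec$name, ]
    purrr::map_dfr(split(est_d, est_d$year), function(est_y) {
      compute_measures_one(est_y, spec, national, measures, sii_scale)
    })
  })

  if (!is.null(records) && boot_B > 0) {
    point <- bootstrap_measure_ci(point, records, dimensions, measures,
                                  sii_scale, boot_B, boot_seed)
  }
  dplyr::arrange(point, .data$dimension, .data$measure, .data$year)
}

# Point-estimate-only recomputation of the measure table for one bootstrap
# replicate: weighted group sums via rowsum, no variance machinery (the
# percentile CIs come from the spread of the replicates themselves).
boot_point_measures <- function(records, dimensions, measures, sii_scale) {
  idx_year <- split(seq_len(nrow(records)), records$survey_year)
  w_all <- records$sampling_weight
  y_all <- records$outcome
  purrr::map_dfr(idx_year, function(ii) {
    w <- w_all[ii]
    wy <- w * y_all[ii]
    tot <- sum(w)
    yr <- records$survey_year[ii[1]]
    nat <- tibble::new_tibble(list(year = yr,
                                   estimate = 100 * sum(wy) / tot),
                              nrow = 1L)
    purrr::map_dfr(dimensions, function(spec) {
      sw <- rowsum(cbind(w, wy), records[[spec$name]][ii])
      k <- nrow(sw)
      est <- tibble::new_tibble(list(
        dimension = rep(spec$name, k), subgroup = rownames(sw),
        year = rep(yr, k),
        estimate = unname(100 * sw[, 2] / sw[, 1]),
        ci_low = rep(NA_real_, k), ci_high = rep(NA_real_, k),
        population_share = unname(sw[, 1] / tot)
      ), nrow = k)
      tryCatch(
        compute_measures_one(est, spec, nat, measures, sii_scale),
        error = function(e) NULL)  # replicate lost a required subgroup
    })
  })
}

# Stratified cluster bootstrap: PSUs are resampled with replacement within
# region strata; the whole estimate->measure pipeline is recomputed on each
# replicate and percentile CIs replace the delta CIs.
bootstrap_measure_ci <- function(point, records, dimensions, measures,
                                 sii_scale, B, seed) {
  set.seed(seed)
  key <- function(d) paste(d$dimension, d$measure, d$year, sep = "\r")
  idx_by_cluster <- split(seq_len(nrow(records)), records$cluster_id)
  cluster_region <- vapply(idx_by_cluster, function(i)
    as.character(records$region[i[1]]), character(1))
  clusters_by_region <- split(names(idx_by_cluster), cluster_region)

  reps <- matrix(NA_real_, nrow = B, ncol = nrow(point))
  colnames(reps) <- key(point)
  for (b in seq_len(B)) {
    take <- unlist(lapply(clusters_by_region, function(cl)
      sample(cl, length(cl), replace = TRUE)), use.names = FALSE)
    rec_b <- records[unlist(idx_by_cluster[take], use.names = FALSE), ]
    m_b <- suppressWarnings(
      boot_point_measures(rec_b, dimensions, measures, sii_scale))
    reps[b, match(key(m_b), colnames(reps))] <- m_b$value_raw
  }
  for (j in seq_len(nrow(point))) {
    if (!point$applicable[j]) next
    v <- reps[, j]
    v <- v[is.finite(v)]
    if (length(v) < B / 2) next
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    point$ci_low[j] <- qs[1]
    point$ci_high[j] <- qs[2]
    point$se[j] <- sd(v)
    point$significant[j] <- qs[1] > point$null_value[j] ||
      qs[2] < point$null_value[j]
  }
  point
}

#' Render the long measure table in the wide year-column layout
#'
#' Values formatted to one decimal place with the 95% CI in parentheses,
#' `NA` for inapplicable cells — the layout used by published inequality
#' tables.
#'
#' @param measure_table Long tibble from [summary_measures()].
#' @return Wide tibble (dimension, measure, one column per year).
#' @export
format_measure_table <- function(measure_table) {
  fmt <- function(v, lo, hi, app) {
    ifelse(!app, "NA",
           ifelse(is.finite(lo),
                  sprintf("%.1f (%.1f, %.1f)", v, lo, hi),
                  sprintf("%.1f", v)))
  }
  measure_table |>
    dplyr::mutate(cell = fmt(.data$value, .data$ci_low, .data$ci_high,
                             .data$applicable)) |>
    dplyr::select("dimension", "measure", "year", "cell") |>
    tidyr::pivot_wider(names_from = "year", values_from = "cell")
}
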