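#' Assess inequality trends across survey years by CI overlap
#'
#' Two survey years differ significantly on a measure when their 95%
#' confidence intervals are disjoint (strictly: touching endpoints count as
#' overlap — a conservative reading of the non-overlap rule). Verdicts are
#' produced for all consecutive year pairs and for the first-to-last
#' (endpoint) pair; inapplicable measure cells are skipped with a note.
#'
#' @param measure_table Long measure tibble (as from [summary_measures()]),
#'   or any tibble with `dimension`, `measure`, `year`, `value`, `ci_low`,
#'   `ci_high` (and optionally `applicable`).
#' @return Tibble of verdicts: `year_a`, `year_b`, `change`
#'   (`value_b - value_a`), `overlapping_ci`, `significant_change`
#'   (`= !overlapping_ci`), `direction`. No multiplicity adjustment is
#'   applied across the pairwise comparisons (recorded in the
#'   `"multiplicity_adjustment"` attribute).
#' @export
assess_trend <- function(measure_table) {
  if (!"applicable" %in% names(measure_table)) {
    measure_table$applicable <- TRUE
  }
  skipped <- measure_table[!measure_table$applicable, ]
  if (nrow(skipped) > 0) {
    inform(paste0("skipping ", nrow(skipped),
                  " inapplicable measure cell(s) in trend assessment"))
  }
  tab <- measure_table[measure_table$applicable, ]
  out <- tab |>
    dplyr::group_split(.data$dimension, .data$measure) |>
    purrr::map_dfr(function(g) {
      g <- dplyr::arrange(g, .data$year)
      if (nrow(g) < 2) return(NULL)
      pairs <- cbind(seq_len(nrow(g) - 1), seq_len(nrow(g) - 1) + 1)
      if (nrow(g) > 2) pairs <- rbind(pairs, c(1, nrow(g)))
      purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
        a <- g[pairs[k, 1], ]
        b <- g[pairs[k, 2], ]
        disjoint <- isTRUE(b$ci_low > a$ci_high) ||
          isTRUE(a$ci_low > b$ci_high)
        change <- b$value - a$value
        tibble::tibble(
          dimension = a$dimension, measure = a$measure,
          year_a = a$year, year_b = b$year,
          comparison = if (pairs[k, 2] - pairs[k, 1] == 1 ||
                           nrow(g) == 2) "consecutive" else "endpoint",
          change = change,
          overlapping_ci = !disjoint,
          significant_change = disjoint,
          direction = if (!disjoint) "flat"
                      else if (change > 0) "increasing" else "decreasing"
        )
      })
    })
  attr(out, "multiplicity_adjustment") <- "none"
  out
}

#' Percentage-point change in national coverage between years
#'
#' @param national National-average tibble (`year`, `estimate`).
#' @param pairs `"all"` for every ordered year pair, `"consecutive"`, or
#'   `"endpoint"` (first vs last only).
#' @return Tibble with `year_a`, `year_b`, `change` in percentage points.
#' @export
coverage_change <- function(national, pairs = c("all", "consecutive",
                                                "endpoint")) {
  pairs <- match.arg(pairs)
  nat <- dplyr::arrange(national, .data$year)
  if (nrow(nat) < 2) abort("need at least two years")
  idx <- switch(pairs,
    all = {
      cmb <- utils::combn(nrow(nat), 2)
      cbind(cmb[1, ], cmb[2, ])
    },
    consecutive = cbind(seq_len(nrow(nat) - 1), seq_len(nrow(nat) - 1) + 1),
    endpoint = cbind(1, nrow(nat))
  )
  tibble::tibble(
    year_a = nat$year[idx[, 1]],
    year_b = nat$year[idx[, 2]],
    estimate_a = nat$estimate[idx[, 1]],
    estimate_b = nat$estimate[idx[, 2]],
    change = nat$estimate[idx[, 2]] - nat$estimate[idx[, 1]]
  )
}

#' Human-readable trend summary
#'
#' @param verdicts Output of [assess_trend()].
#' @return Character vector (one block per dimension) suitable for writing
#'   to a report.
#' @export
trend_summary_text <- function(verdicts) {
  vapply(split(verdicts, verdicts$dimension), function(v) {
    lines <- sprintf(
      "  %s %s->%s: change %+0.1f, %s",
      format(v$measure, width = 4), v$year_a, v$year_b, v$change,
      ifelse(v$significant_change,
             paste0("significant (", v$direction, ")"),
             "not significant (CIs overlap)")
    )
    paste0(v$dimension[1], ":\n", paste(lines, collapse = "\n"))
  }, character(1))
}
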