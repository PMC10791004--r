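#' Configure an end-to-end analysis run
#'
#' Exactly one input mode is used: `"synthetic"` (generate surveys from a
#' [synthetic_config()]), `"records_csv"` (child-level records on disk), or
#' `"estimates_csv"` (a pre-disaggregated estimate table plus national
#' averages — the measure engine then runs without the record-level
#' stages).
#'
#' @param mode Input mode.
#' @param out_dir Output directory (created if absent).
#' @param synth [synthetic_config()] for synthetic mode.
#' @param records_csv,estimates_csv,national_csv Input paths for the CSV
#'   modes.
#' @param dimensions Optional list of [dimension_spec()]s.
#' @param measures Measures to compute.
#' @param boot_B Bootstrap replicates for record-level measure CIs.
#' @param seed Top-level seed: all randomness (generation and bootstrap)
#'   flows from it.
#' @param multilevel Fit the two-level determinants model (record-level
#'   modes only).
#' @param verbose Log progress to stderr.
#' @return List of class `equicov_run_config`.
#' @export
run_config <- function(mode = c("synthetic", "records_csv", "estimates_csv"),
                       out_dir = "equicov-out",
                       synth = synthetic_config(),
                       records_csv = NULL,
                       estimates_csv = NULL,
                       national_csv = NULL,
                       dimensions = NULL,
                       measures = ALL_MEASURES,
                       boot_B = 200,
                       seed = 20260101L,
                       multilevel = TRUE,
                       verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "records_csv" && is.null(records_csv)) {
    abort("records_csv mode needs a records_csv path")
  }
  if (mode == "estimates_csv" &&
      (is.null(estimates_csv) || is.null(national_csv))) {
    abort("estimates_csv mode needs estimates_csv and national_csv paths")
  }
  structure(
    list(mode = mode, out_dir = out_dir, synth = synth,
         records_csv = records_csv, estimates_csv = estimates_csv,
         national_csv = national_csv, dimensions = dimensions,
         measures = measures, boot_B = boot_B, seed = as.integer(seed),
         multilevel = multilevel, verbose = verbose),
    class = "equicov_run_config"
  )
}

#' Run the full inequality-analysis pipeline
#'
#' Generate or ingest data, disaggregate by the equity stratifiers, compute
#' the six summary measures, build concentration and Lorenz curves
#' (record-level modes), assess cross-year trends, fit the two-level
#' determinants model (record-level modes), and write every table plus a
#' run manifest into `config$out_dir`. On failure all partial outputs are
#' removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every computed table and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "equicov_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[equicov] ", ...)
  written <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  t0 <- Sys.time()

  result <- tryCatch({
    records <- NULL
    if (config$mode == "synthetic") {
      say("generating synthetic surveys (seed ", config$seed, ")")
      synth <- config$synth
      synth$seed <- config$seed
      records <- generate_surveys(synth)
      write_children_csv(records, out("children.csv"))
      write_config(synth, out("synthetic_config.yaml"))
    } else if (config$mode == "records_csv") {
      say("reading child records from ", config$records_csv)
      records <- read_children_csv(config$records_csv)
    }

    if (!is.null(records)) {
      dims <- config$dimensions %||%
        default_dimensions(regions = sort(unique(records$region)))
      dims <- dims[vapply(dims, function(d) d$name %in% names(records),
                          logical(1))]
      say("disaggregating ", nrow(records), " records")
      estimates <- disaggregate(records, dims)
      national <- weighted_prevalence(records)
      say("summary measures (bootstrap B = ", config$boot_B, ")")
      meas <- summary_measures(estimates, national, dims,
                               measures = config$measures,
                               records = records,
                               boot_B = config$boot_B,
                               boot_seed = config$seed + 1L)
    } else {
      estimates <- read_estimates_csv(config$estimates_csv)
      national <- read_national_csv(config$national_csv)
      dims <- config$dimensions
      say("summary measures from estimate table")
      meas <- summary_measures(estimates, national, dims,
                               measures = config$measures)
    }
    write.csv(estimates, out("estimates.csv"), row.names = FALSE)
    write.csv(national, out("national.csv"), row.names = FALSE)
    write.csv(meas, out("measures.csv"), row.names = FALSE)
    write.csv(format_measure_table(meas), out("measures_wide.csv"),
              row.names = FALSE)

    say("trend assessment")
    trends <- suppressMessages(assess_trend(meas))
    write.csv(trends, out("trends.csv"), row.names = FALSE)
    writeLines(trend_summary_text(trends), out("trends_summary.txt"))
    cov_chg <- coverage_change(national)
    write.csv(cov_chg, out("coverage_change.csv"), row.names = FALSE)

    curves <- NULL
    mlfit <- NULL
    if (!is.null(records)) {
      say("concentration and Lorenz curves")
      rank_var <- if ("asset_score" %in% names(records)) "asset_score"
                  else "wealth_quintile"
      curves <- lapply(split(records, records$survey_year), function(rec) {
        rk <- if (rank_var == "asset_score") rec$asset_score
              else as.integer(factor(rec$wealth_quintile))
        concentration_curve(rec$outcome, rk, rec$sampling_weight,
                            ranking_variable = rank_var)
      })
      for (yr in names(curves)) {
        write_curve_csv(curves[[yr]],
                        out(paste0("concentration_curve_", yr, ".csv")))
      }
      if (config$multilevel) {
        say("two-level determinants model")
        mlspec <- multilevel_spec(
          community_terms = intersect(c("survey_year", "region", "residence"),
                                      names(records)),
          individual_terms = intersect(
            c("wealth_quintile", "maternal_education", "maternal_age",
              "sex", "birth_order", "anc_visits", "facility_delivery"),
            names(records))
        )
        if (length(unique(records$survey_year)) < 2) {
          mlspec$community_terms <-
            setdiff(mlspec$community_terms, "survey_year")
        }
        mlfit <- fit_multilevel(records, mlspec)
        write_multilevel_csv(mlfit, out("multilevel_or.csv"),
                             out("multilevel_meta.json"))
      }
    }

    manifest <- list(
      package = "equicov",
      version = as.character(packageVersion("equicov")),
      mode = config$mode,
      seed = config$seed,
      n_records = if (!is.null(records)) nrow(records) else NA,
      measures = config$measures,
      boot_B = if (!is.null(records)) config$boot_B else NA,
      outputs = basename(written),
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say(sprintf("done in %.1f s", manifest$elapsed_sec))
    list(records = records, estimates = estimates, national = national,
         measures = meas, trends = trends, coverage_change = cov_chg,
         curves = curves, multilevel = mlfit, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    abort(paste("pipeline failed (partial outputs removed):",
                conditionMessage(e)))
  })
  invisible(result)
}
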