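#' Read a pre-disaggregated subgroup-estimate table
#'
#' Reads the long CSV schema `dimension, subgroup, year, estimate, ci_low,
#' ci_high, population_share` (percent scale for the estimate and CI
#' bounds, proportions for the shares), so that published disaggregated
#' coverage tables can be fed to the measure engine directly. Rows whose CI
#' bounds do not bracket the estimate are rejected with their row number;
#' population shares are validated to sum to 1 within each dimension-year
#' (within 0.005 silently, within 0.05 with a warning, beyond that an
#' error).
#'
#' @param path CSV path (lines starting with `#` are treated as comments).
#' @return Tibble of subgroup estimates.
#' @export
read_estimates_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("dimension", "subgroup", "year", "estimate", "ci_low",
            "ci_high", "population_share")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste("estimate CSV is missing columns:",
                paste(missing, collapse = ", ")))
  }
  if (anyNA(df$ci_low) || anyNA(df$ci_high)) {
    warn("missing CI bounds: delta-method CIs will be unavailable for those rows")
  }
  bad <- which(df$ci_low > df$estimate | df$estimate > df$ci_high)
  if (length(bad)) {
    abort(paste0("CI bounds do not bracket the estimate in row(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(df$estimate < 0 | df$estimate > 100)) {
    abort("estimates must lie in [0, 100]")
  }
  sums <- aggregate(population_share ~ dimension + year, df, sum)
  dev <- abs(sums$population_share - 1)
  if (any(dev > 0.05)) {
    bad <- sums[dev > 0.05, ]
    abort(paste0("population shares far from 1 for ",
                 paste(bad$dimension, bad$year, collapse = "; ")))
  }
  if (any(dev > 0.005)) {
    bad <- sums[dev > 0.005, ]
    warn(paste0("population shares deviate from 1 (tolerance) for: ",
                paste(bad$dimension, bad$year,
                      sprintf("(sum %.3f)", bad$population_share),
                      collapse = "; ")))
  }
  tibble::as_tibble(df)
}

#' Read a national-average table
#'
#' Schema: `year, estimate` (percent), optional `ci_low`, `ci_high`, `n`.
#' @param path CSV path.
#' @return Tibble of national averages.
#' @export
read_national_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("year", "estimate") %in% names(df))) {
    abort("national CSV needs columns year, estimate")
  }
  if (any(df$estimate < 0 | df$estimate > 100)) {
    abort("national estimates must lie in [0, 100]")
  }
  tibble::as_tibble(df)
}

#' Published DPT3 disaggregated coverage, Ethiopia 2000-2019
#'
#' The disaggregated DPT3 immunization estimates (subgroup percentage, 95%
#' CI and population share, by wealth quintile, maternal education,
#' residence, sex and subnational region) and the national coverage series
#' for the five Ethiopian Demographic and Health Survey rounds, as
#' published via the WHO Health Equity Monitor. Bundled as plain CSV under
#' `inst/extdata/`; transcription notes are in the file headers.
#'
#' @return `edhs_dpt3_estimates()`: subgroup-estimate tibble;
#'   `edhs_dpt3_national()`: national-average tibble.
#' @export
edhs_dpt3_estimates <- function() {
  suppressWarnings(read_estimates_csv(
    system.file("extdata", "edhs_dpt3_subgroup_estimates.csv",
                package = "equicov", mustWork = TRUE)))
}

#' @rdname edhs_dpt3_estimates
#' @export
edhs_dpt3_national <- function() {
  read_national_csv(system.file("extdata", "edhs_dpt3_national.csv",
                                package = "equicov", mustWork = TRUE))
}

#' Write / read a run or generator configuration as YAML or JSON
#'
#' @param config A list (e.g. [synthetic_config()] or [run_config()]).
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return `path` (writer) / list (reader).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("config path must end in .yaml/.yml or .json")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config path must end in .yaml/.yml or .json")
  }
}
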