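#' Configuration for the synthetic two-stage cluster survey generator
#'
#' Describes a DHS-like sampling design and outcome model: region strata,
#' primary sampling units (PSUs, "clusters") drawn with probability
#' proportional to size, a fixed number of households per PSU, and a
#' child-level Bernoulli outcome whose log-odds combine a region baseline, a
#' Normal PSU random intercept, and individual covariate effects. The
#' defaults emulate the qualitative structure of a recent national
#' immunization survey in a low-income, highly regionalized setting: a
#' pro-rich and pro-educated coverage gradient, urban above rural, strong
#' regional heterogeneity, and no effect of child sex.
#'
#' @param n_regions Number of region strata.
#' @param clusters_per_region PSUs sampled per region.
#' @param households_per_cluster Households recruited per PSU (DHS practice
#'   is a fixed take of 28-30).
#' @param children_prob Probabilities of a household contributing 0, 1 or 2
#'   age-eligible children (one-child households dominate in a 12-month age
#'   band).
#' @param region_log_odds Per-region baseline log-odds of the outcome
#'   (length `n_regions`).
#' @param beta_wealth Log-odds increment per wealth-quintile step (Q1 -> Q5
#'   spans `4 * beta_wealth`).
#' @param beta_education Log-odds increment per maternal education level
#'   (none = 0, primary = 1, secondary+ = 2).
#' @param beta_urban Log-odds increment for urban residence.
#' @param beta_sex Log-odds increment for male sex (default 0: sex-null).
#' @param beta_age Log-odds per year of maternal age (centred at 28).
#' @param beta_anc Log-odds per antenatal-care visit.
#' @param beta_facility_delivery Log-odds increment for facility delivery.
#' @param beta_birth_order Log-odds per birth-order step above 1.
#' @param cluster_sd Standard deviation of the PSU-level random intercept;
#'   controls the intraclass correlation `cluster_sd^2 / (cluster_sd^2 +
#'   pi^2/3)` on the latent scale (default 0.9, ICC ~ 0.20).
#' @param urban_fraction_by_region Probability that a PSU in each region is
#'   urban (length `n_regions`; the last region defaults to fully urban,
#'   like a capital-city administration).
#' @param survey_years Vector of year labels the generator can produce.
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return A validated list of class `equicov_synth_config`.
#' @export
synthetic_config <- function(n_regions = 11,
                             clusters_per_region = 20,
                             households_per_cluster = 29,
                             children_prob = c(0.55, 0.40, 0.05),
                             region_log_odds = c(-1.9, -1.4, -1.0, -0.6,
                                                 -0.4, -0.2, 0.1, 0.4,
                                                 0.9, 1.5, 2.2),
                             beta_wealth = 0.18,
                             beta_education = 0.35,
                             beta_urban = 0.4,
                             beta_sex = 0,
                             beta_age = 0.02,
                             beta_anc = 0.15,
                             beta_facility_delivery = 0.2,
                             beta_birth_order = -0.1,
                             cluster_sd = 0.9,
                             urban_fraction_by_region = c(0.08, 0.08, 0.10,
                                                          0.10, 0.12, 0.12,
                                                          0.15, 0.15, 0.25,
                                                          0.40, 1.00),
                             survey_years = c(2000, 2005, 2011, 2016, 2019),
                             seed = 20260101L) {
  cfg <- list(
    n_regions = n_regions,
    clusters_per_region = clusters_per_region,
    households_per_cluster = households_per_cluster,
    children_prob = children_prob,
    region_log_odds = region_log_odds,
    beta_wealth = beta_wealth,
    beta_education = beta_education,
    beta_urban = beta_urban,
    beta_sex = beta_sex,
    beta_age = beta_age,
    beta_anc = beta_anc,
    beta_facility_delivery = beta_facility_delivery,
    beta_birth_order = beta_birth_order,
    cluster_sd = cluster_sd,
    urban_fraction_by_region = urban_fraction_by_region,
    survey_years = survey_years,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "equicov_synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$region_log_odds) != cfg$n_regions) {
    abort("region_log_odds must have length n_regions")
  }
  if (length(cfg$urban_fraction_by_region) != cfg$n_regions) {
    abort("urban_fraction_by_region must have length n_regions")
  }
  if (cfg$cluster_sd < 0) abort("cluster_sd must be >= 0")
  if (any(cfg$urban_fraction_by_region < 0 | cfg$urban_fraction_by_region > 1)) {
    abort("urban fractions must lie in [0, 1]")
  }
  if (abs(sum(cfg$children_prob) - 1) > 1e-8 || any(cfg$children_prob < 0)) {
    abort("children_prob must be a probability vector")
  }
  if (cfg$n_regions < 1 || cfg$clusters_per_region < 1 ||
      cfg$households_per_cluster < 1) {
    abort("design counts must be positive")
  }
  invisible(cfg)
}

#' Assign weighted wealth quintiles from a latent asset score
#'
#' Households (or children) are ordered by their asset score and walked in
#' cumulative-weight order; each unit is labelled by the fifth of total
#' weight that contains the midpoint of its own weight interval. Each
#' quintile therefore holds 20% of total weight up to at most one unit's
#' weight; ties in the score keep stable input order.
#'
#' @param asset_scores Numeric latent wealth scores.
#' @param weights Positive sampling weights (default: equal).
#' @return Ordered factor with levels `Q1` (poorest) to `Q5` (richest).
#' @examples
#' quintile_assign(1:10)  # two units per quintile
#' @export
quintile_assign <- function(asset_scores, weights = NULL) {
  n <- length(asset_scores)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) abort("asset_scores and weights differ in length")
  if (any(weights <= 0)) abort("weights must be positive")
  if (length(unique(asset_scores)) < 5) {
    abort("need at least 5 distinct asset scores to form quintiles")
  }
  ord <- order(asset_scores)        # stable: ties keep input order
  w <- weights[ord]
  cum_before <- cumsum(w) - w
  mid <- (cum_before + w / 2) / sum(w)
  q <- pmin(5L, pmax(1L, ceiling(5 * mid)))
  out <- integer(n)
  out[ord] <- q
  factor(paste0("Q", out), levels = paste0("Q", 1:5), ordered = TRUE)
}

#' Generate one synthetic child-level survey
#'
#' Draws a two-stage cluster sample and a binary outcome for every child
#' aged 12-23 months: (1) PSUs are selected within region strata with
#' probability proportional to simulated cluster size; (2) a fixed number of
#' households is recruited per PSU; (3) each household receives a latent
#' continuous asset score (region- and residence-shifted) which is converted
#' to weighted quintiles over the whole sample; (4) maternal education is
#' drawn with probabilities monotone in the asset score; (5) the outcome is
#' Bernoulli with logit = region baseline + PSU random intercept +
#' covariate terms; (6) the sampling weight is the inverse of the product of
#' the two stage-selection probabilities, normalized to mean 1.
#'
#' @param config A [synthetic_config()].
#' @param year One of `config$survey_years`; shifts the stream of random
#'   numbers so different years give independent samples.
#' @return A tibble with one row per child: `child_id`, `survey_year`,
#'   `region`, `residence`, `cluster_id`, `household_id`, `wealth_quintile`,
#'   `asset_score`, `maternal_education`, `sex`, `maternal_age`,
#'   `birth_order`, `anc_visits`, `facility_delivery`, `sampling_weight`,
#'   `outcome`.
#' @export
generate_population <- function(config, year = config$survey_years[1]) {
  validate_synth_config(config)
  yi <- match(year, config$survey_years)
  if (is.na(yi)) abort("year is not in config$survey_years")
  set.seed(config$seed + 7919L * yi)

  regions <- sprintf("R%02d", seq_len(config$n_regions))
  m <- config$clusters_per_region
  h <- config$households_per_cluster

  clusters <- purrr::map_dfr(seq_len(config$n_regions), function(r) {
    # simulated PSU frame: candidate enumeration areas with household counts
    n_frame <- max(6L * m, 60L)
    frame_size <- pmax(40L, round(exp(rnorm(n_frame, log(150), 0.35))))
    pick <- sample.int(n_frame, m, prob = frame_size)
    p1 <- pmin(1, m * frame_size[pick] / sum(frame_size))  # PPS approx
    tibble::tibble(
      region = regions[r],
      # PSUs are drawn fresh each survey round, so IDs carry the year
      cluster_id = sprintf("%s_%s_C%03d", year, regions[r], seq_len(m)),
      frame_households = frame_size[pick],
      p_stage1 = p1,
      urban = rbinom(m, 1, config$urban_fraction_by_region[r]),
      re_cluster = rnorm(m, 0, config$cluster_sd)
    )
  })
  clusters$p_stage2 <- pmin(1, h / clusters$frame_households)

  hh <- clusters[rep(seq_len(nrow(clusters)), each = h), ]
  hh$household_id <- paste0(hh$cluster_id, "_H", rep(seq_len(h), nrow(clusters)))
  region_idx <- match(hh$region, regions)
  hh$asset <- 0.25 * config$region_log_odds[region_idx] +
    1.0 * hh$urban + rnorm(nrow(hh))
  n_child <- sample(0:2, nrow(hh), replace = TRUE, prob = config$children_prob)

  kid <- hh[rep(seq_len(nrow(hh)), times = n_child), ]
  if (nrow(kid) == 0) abort("configuration produced an empty sample")
  n <- nrow(kid)
  kid$weight_raw <- 1 / (kid$p_stage1 * kid$p_stage2)
  kid$sampling_weight <- kid$weight_raw * n / sum(kid$weight_raw)

  wq <- quintile_assign(kid$asset, kid$sampling_weight)
  # education: cumulative-logit draw, monotone in the asset score
  p_none <- plogis(0 - kid$asset)
  p_le_prim <- plogis(1.6 - kid$asset)
  u <- runif(n)
  educ <- ifelse(u < p_none, "none",
                 ifelse(u < p_le_prim, "primary", "secondary+"))
  sex <- ifelse(rbinom(n, 1, 0.512) == 1, "male", "female")
  age <- pmin(49, pmax(15, round(rnorm(n, 28, 6))))
  border <- 1 + rpois(n, 1.5)
  anc <- rpois(n, exp(0.6 + 0.25 * kid$asset))
  fd <- rbinom(n, 1, plogis(-0.8 + 0.8 * kid$asset + 0.8 * kid$urban))

  lp <- config$region_log_odds[match(kid$region, regions)] +
    kid$re_cluster +
    config$beta_wealth * (as.integer(wq) - 1) +
    config$beta_education * match(educ, c("none", "primary", "secondary+")) -
    config$beta_education +
    config$beta_urban * kid$urban +
    config$beta_sex * (sex == "male") +
    config$beta_age * (age - 28) +
    config$beta_anc * anc +
    config$beta_facility_delivery * fd +
    config$beta_birth_order * (border - 1)
  if (any(!is.finite(lp))) abort("non-finite logit: miscalibrated configuration")

  tibble::tibble(
    child_id = sprintf("%s_%s_K%05d", year, kid$region, seq_len(n)),
    survey_year = year,
    region = kid$region,
    residence = ifelse(kid$urban == 1, "urban", "rural"),
    cluster_id = kid$cluster_id,
    household_id = kid$household_id,
    wealth_quintile = as.character(wq),
    asset_score = kid$asset,
    maternal_education = educ,
    sex = sex,
    maternal_age = age,
    birth_order = border,
    anc_visits = anc,
    facility_delivery = fd,
    sampling_weight = kid$sampling_weight,
    outcome = rbinom(n, 1, plogis(lp))
  )
}

#' Generate all survey rounds of a configuration
#'
#' @param config A [synthetic_config()].
#' @return Tibble of child records for every year in `config$survey_years`.
#' @export
generate_surveys <- function(config) {
  purrr::map_dfr(config$survey_years,
                 function(y) generate_population(config, y))
}

# Fixed column order for the child-level CSV interchange format
child_csv_columns <- c(
  "child_id", "survey_year", "region", "residence", "cluster_id",
  "household_id", "wealth_quintile", "asset_score", "maternal_education",
  "sex", "maternal_age", "birth_order", "anc_visits", "facility_delivery",
  "sampling_weight", "outcome"
)

#' Write / read child-level records as CSV
#'
#' The file uses a fixed, documented column order so that downstream tools
#' can rely on the schema.
#' @param records Child-record tibble (from [generate_population()] or
#'   compatible).
#' @param path File path.
#' @return `path` (writer) / record tibble (reader), invisibly for the
#'   writer.
#' @export
write_children_csv <- function(records, path) {
  missing <- setdiff(setdiff(child_csv_columns, "asset_score"),
                     names(records))
  if (length(missing)) {
    abort(paste("records are missing columns:", paste(missing, collapse = ", ")))
  }
  cols <- intersect(child_csv_columns, names(records))
  write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_children_csv
#' @export
read_children_csv <- function(path) {
  rec <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("outcome", "sampling_weight", "cluster_id", "survey_year")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    abort(paste("child CSV is missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(rec$sampling_weight <= 0)) abort("sampling weights must be positive")
  if (!all(rec$outcome %in% c(0, 1))) abort("outcome must be binary 0/1")
  rec
}

#' Summarize a generated survey (generation log)
#'
#' @param records Child records.
#' @param config The generating configuration (for the seed).
#' @return List with the seed, realized sample size and weighted coverage by
#'   dimension.
#' @export
generation_log <- function(records, config = NULL) {
  dims <- intersect(c("wealth_quintile", "maternal_education", "residence",
                      "sex", "region"), names(records))
  cov_by <- lapply(dims, function(d) {
    s <- split(records, records[[d]])
    vapply(s, function(x) {
      100 * weighted.mean(x$outcome, x$sampling_weight)
    }, numeric(1))
  })
  names(cov_by) <- dims
  list(
    seed = if (!is.null(config)) config$seed else NA_integer_,
    n = nrow(records),
    years = sort(unique(records$survey_year)),
    national_coverage = 100 * weighted.mean(records$outcome,
                                            records$sampling_weight),
    coverage_by_dimension = cov_by
  )
}
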