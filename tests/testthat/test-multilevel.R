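small_ml_spec <- multilevel_spec(
  community_terms = c("region", "residence"),
  individual_terms = c("sex", "maternal_age", "facility_delivery")
)

test_that("null data recover a null: sex OR covers 1, variance near zero", {
  cfg <- null_config(seed = 51, clusters_per_region = 40)
  rec <- generate_population(cfg, 2000)
  fit <- fit_multilevel(rec, small_ml_spec)
  sexrow <- fit$fixed_effects[fit$fixed_effects$term == "sex", ]
  expect_true(sexrow$ci_low <= 1 && 1 <= sexrow$ci_high)
  expect_lt(fit$random_intercept_variance, 0.1)
  expect_lt(fit$icc, 0.03)
  expect_true(fit$converged)
})

test_that("with no true clustering the mixed fit matches a plain glm", {
  cfg <- null_config(seed = 52, clusters_per_region = 20)
  cfg$beta_urban <- 0.4
  cfg$beta_facility_delivery <- 0.3
  rec <- generate_population(cfg, 2000)
  mixed <- fit_multilevel(rec, small_ml_spec)
  plain <- fit_multilevel(rec, {
    s <- small_ml_spec
    s$grouping <- NULL
    s
  })
  m <- mixed$fixed_effects$estimate
  p <- plain$fixed_effects$estimate
  expect_equal(m, p, tolerance = 0.05)
  # and the oracle glm gives the same single-level answer
  g <- glm(outcome ~ region + residence + sex + maternal_age +
             facility_delivery, binomial(), data = rec)
  expect_equal(unname(p), unname(coef(g)), tolerance = 1e-8)
})

test_that("switching the reference level inverts the odds ratio", {
  cfg <- synthetic_config(seed = 53, clusters_per_region = 15)
  rec <- generate_population(cfg, 2019)
  f1 <- fit_multilevel(rec, small_ml_spec)
  spec2 <- small_ml_spec
  spec2$reference_levels <- list(residence = "urban")
  f2 <- fit_multilevel(rec, spec2)
  or1 <- f1$fixed_effects$or[f1$fixed_effects$coefficient == "residenceurban"]
  or2 <- f2$fixed_effects$or[f2$fixed_effects$coefficient == "residencerural"]
  expect_equal(or2, 1 / or1, tolerance = 1e-3)
})

test_that("degenerate designs are rejected, not absorbed", {
  rec <- generate_population(synthetic_config(seed = 54,
                                              clusters_per_region = 5), 2019)
  rec$constant_term <- 1
  spec <- multilevel_spec(community_terms = "residence",
                          individual_terms = c("sex", "constant_term"))
  expect_error(fit_multilevel(rec, spec), "constant")

  rec$dup <- rec$facility_delivery
  spec2 <- multilevel_spec(community_terms = "residence",
                           individual_terms = c("facility_delivery", "dup"))
  expect_error(fit_multilevel(rec, spec2), "rank deficient")

  expect_error(
    fit_multilevel(rec, multilevel_spec(
      community_terms = "residence", individual_terms = "sex",
      reference_levels = list(sex = "nonexistent"))),
    "reference level"
  )
})

test_that("Laplace/AGQ log-likelihood matches brute-force Gauss-Hermite", {
  # tiny fixed dataset so plain quadrature with many nodes is exact
  set.seed(55)
  n_cl <- 12
  per <- 12
  cl <- rep(sprintf("c%02d", 1:n_cl), each = per)
  x <- rnorm(n_cl * per)
  b <- rep(rnorm(n_cl, 0, 0.8), each = per)
  y <- rbinom(n_cl * per, 1, plogis(-0.3 + 0.7 * x + b))
  dat <- tibble::tibble(outcome = y, x = x, cluster_id = cl)
  spec <- multilevel_spec(community_terms = character(0),
                          individual_terms = "x")
  fit <- fit_multilevel(dat, spec, nAGQ = 25)
  beta <- fit$fixed_effects$estimate
  eta <- beta[1] + beta[2] * x
  sigma <- sqrt(fit$random_intercept_variance)
  ll_oracle <- marginal_loglik_gh(y, eta, cl, sigma, k = 201)
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-4)
})

test_that("ICC follows the latent-scale identity and the OR table is sane", {
  rec <- generate_population(synthetic_config(seed = 56,
                                              clusters_per_region = 10), 2019)
  fit <- fit_multilevel(rec, small_ml_spec)
  expect_equal(fit$icc,
               fit$random_intercept_variance /
                 (fit$random_intercept_variance + pi^2 / 3))
  fx <- fit$fixed_effects
  expect_true(all(fx$or > 0))
  expect_true(all(fx$ci_low <= fx$or & fx$or <= fx$ci_high))
  expect_equal(fit$n_obs, nrow(rec))
  expect_equal(fit$n_groups, length(unique(rec$cluster_id)))

  path <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_multilevel_csv(fit, path, meta)
  or_tab <- read.csv(path)
  expect_true(all(c("term", "level", "or") %in% names(or_tab)))
  m <- jsonlite::read_json(meta)
  expect_equal(m$n_obs, nrow(rec))
})
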