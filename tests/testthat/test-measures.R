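# Small helper: estimate table for one ordered dimension-year, with CI
# bounds wide enough to carry a known SE when needed.
ord_spec3 <- dimension_spec("grad", "ordered", c("low", "mid", "high"))

make_est <- function(subgroups, estimates, shares, year = 2000,
                     dimension = "grad", half_width = 2) {
  tibble::tibble(
    dimension = dimension, subgroup = subgroups, year = year,
    estimate = estimates,
    ci_low = estimates - half_width, ci_high = estimates + half_width,
    population_share = shares
  )
}

test_that("difference and ratio reproduce published table cells", {
  meas <- paper_measures
  expect_equal(measure_cell(meas, "maternal_education", "D", 2000), 37.6,
               tolerance = 1e-10)
  expect_equal(measure_cell(meas, "sex", "D", 2000), -3.4,
               tolerance = 1e-10)
  expect_equal(measure_cell(meas, "residence", "R", 2000), 51.4 / 17.6,
               tolerance = 1e-10)
  expect_equal(measure_cell(meas, "region", "D", 2000), 80.9 - 1.1,
               tolerance = 1e-10)
  expect_equal(measure_cell(meas, "region", "R", 2011), 89.2 / 11.6,
               tolerance = 1e-10)
})

test_that("identical subgroup estimates give null D and R", {
  est <- make_est(c("low", "mid", "high"), rep(40, 3), rep(1 / 3, 3))
  d <- inequality_difference(est, ord_spec3)
  expect_equal(d$value, 0)
  expect_false(d$significant)
  r <- inequality_ratio(est, ord_spec3)
  expect_equal(r$value, 1)
  expect_false(r$significant)
})

test_that("SII/RII match closed forms and the WLS normal-equations oracle", {
  # two equal halves at 20 and 40: midpoints 0.25/0.75, fitted v0 = 10,
  # v1 = 50, so SII = 2 * (40 - 20) = 40 and RII = 5
  est2 <- make_est(c("low", "high"), c(20, 40), c(0.5, 0.5))
  sii <- slope_index(est2, ord_spec3)
  expect_equal(sii$value, 40, tolerance = 1e-10)
  rii <- relative_index(est2, ord_spec3)
  expect_equal(rii$value, 5, tolerance = 1e-10)

  # five equal-share quintiles with a linear gradient
  q_spec <- dimension_spec("grad", "ordered", paste0("g", 1:5))
  est5 <- make_est(paste0("g", 1:5), c(10, 20, 30, 40, 50), rep(0.2, 5))
  sii5 <- slope_index(est5, q_spec)
  oracle <- wls_oracle(rep(0.2, 5), c(10, 20, 30, 40, 50))
  expect_equal(sii5$value, oracle$v1 - oracle$v0, tolerance = 1e-10)
  expect_equal(sii5$value, 50, tolerance = 1e-10)
  rii5 <- relative_index(est5, q_spec)
  expect_equal(rii5$value, oracle$v1 / oracle$v0, tolerance = 1e-10)

  # unequal shares: oracle agreement is the real check
  est_u <- make_est(c("low", "mid", "high"), c(16.3, 35, 53.9),
                    c(0.796, 0.149, 0.055))
  o_u <- wls_oracle(c(0.796, 0.149, 0.055), c(16.3, 35, 53.9))
  expect_equal(slope_index(est_u, ord_spec3)$value, o_u$v1 - o_u$v0,
               tolerance = 1e-9)

  # flat gradient
  est_f <- make_est(c("low", "mid", "high"), rep(33, 3), rep(1 / 3, 3))
  expect_equal(slope_index(est_f, ord_spec3)$value, 0, tolerance = 1e-10)
  expect_equal(relative_index(est_f, ord_spec3)$value, 1, tolerance = 1e-10)
})

test_that("SII/RII are inapplicable off the ordered dimensions (NA pattern)", {
  meas <- paper_measures
  for (d in c("residence", "sex")) {
    for (m in c("SII", "RII")) {
      cells <- meas[meas$dimension == d & meas$measure == m, ]
      expect_equal(nrow(cells), 5)
      expect_true(all(!cells$applicable))
      expect_true(all(is.na(cells$value)))
    }
  }
  # ordered dimensions do get SII/RII
  expect_true(all(meas$applicable[meas$dimension == "maternal_education" &
                                    meas$measure == "SII"]))
})

test_that("PAR uses the reference rules, floors at zero; PAF identity", {
  meas <- paper_measures
  # best-performing region vs national average
  expect_equal(measure_cell(meas, "region", "PAR", 2011), 89.2 - 37,
               tolerance = 1e-10)
  expect_equal(measure_cell(meas, "region", "PAR", 2011, "reference_subgroup"),
               "Addis Ababa")
  # sex reference = female
  expect_equal(measure_cell(meas, "sex", "PAR", 2011), 39.3 - 37,
               tolerance = 1e-10)
  # floored when the reference sits below the national average
  expect_equal(measure_cell(meas, "sex", "PAR", 2019), 0)
  expect_equal(measure_cell(meas, "sex", "PAR", 2019, "value_raw"),
               60.1 - 62, tolerance = 1e-10)
  expect_equal(measure_cell(meas, "sex", "PAR", 2000), 0)

  # PAF = 100 * PAR / mu on unrounded internals, for every cell
  par <- meas[meas$measure == "PAR", ]
  paf <- meas[meas$measure == "PAF", ]
  key <- function(x) paste(x$dimension, x$year)
  paf <- paf[match(key(par), key(paf)), ]
  mu <- paper_national$estimate[match(par$year, paper_national$year)]
  expect_equal(paf$value, 100 * par$value / mu, tolerance = 1e-12)
})

test_that("simple-measure consistency: R > 1 iff D > 0; class tags", {
  meas <- paper_measures
  d <- meas[meas$measure == "D", ]
  r <- meas[meas$measure == "R", ]
  key <- function(x) paste(x$dimension, x$year)
  r <- r[match(key(d), key(r)), ]
  expect_true(all((r$value > 1) == (d$value > 0)))

  tags <- unique(meas[, c("measure", "measure_type", "measure_complexity")])
  expect_equal(tags$measure_type[match(c("D", "SII", "PAR"), tags$measure)],
               rep("absolute", 3))
  expect_equal(tags$measure_type[match(c("R", "RII", "PAF"), tags$measure)],
               rep("relative", 3))
  expect_equal(tags$measure_complexity[match(c("D", "R"), tags$measure)],
               rep("simple", 2))
})

test_that("sign(D) = sign(SII) on monotone synthetic gradients", {
  rec <- generate_population(synthetic_config(seed = 77), 2019)
  meas <- summary_measures(records = rec, boot_B = 0)
  for (d in c("wealth_quintile", "maternal_education")) {
    dv <- measure_cell(meas, d, "D", 2019)
    sv <- measure_cell(meas, d, "SII", 2019)
    expect_equal(sign(dv), sign(sv))
  }
})

test_that("delta-method CIs approximate the published measure intervals", {
  meas <- paper_measures
  # education D 2000 printed as 37.6 (22.2, 53.1)
  expect_equal(measure_cell(meas, "maternal_education", "D", 2000, "ci_low"),
               22.2, tolerance = 0.5)
  expect_equal(measure_cell(meas, "maternal_education", "D", 2000, "ci_high"),
               53.1, tolerance = 0.5)
  expect_true(measure_cell(meas, "maternal_education", "D", 2000,
                           "significant"))
  # sex D 2000 printed as -3.4 (-8.4, 1.6): not significant
  expect_false(measure_cell(meas, "sex", "D", 2000, "significant"))
})

test_that("cluster-bootstrap CIs bracket the point estimates", {
  cfg <- synthetic_config(seed = 13, clusters_per_region = 8)
  rec <- generate_population(cfg, 2019)
  dims <- default_dimensions(regions = sort(unique(rec$region)))
  dims <- dims[c("wealth_quintile", "residence")]
  meas <- summary_measures(records = rec, dimensions = dims,
                           boot_B = 80, boot_seed = 5)
  app <- meas[meas$applicable & is.finite(meas$ci_low), ]
  expect_gt(nrow(app), 0)
  expect_true(all(app$ci_low <= app$ci_high))
  expect_true(all(app$ci_low <= app$value_raw & app$value_raw <= app$ci_high))
})

test_that("bootstrap CIs are reproducible given the seed", {
  cfg <- synthetic_config(seed = 13, clusters_per_region = 6)
  rec <- generate_population(cfg, 2019)
  dims <- default_dimensions()["residence"]
  m1 <- summary_measures(records = rec, dimensions = dims,
                         boot_B = 40, boot_seed = 9)
  m2 <- summary_measures(records = rec, dimensions = dims,
                         boot_B = 40, boot_seed = 9)
  expect_identical(m1, m2)
})

test_that("logit-scale ridit regression variant stays within bounds", {
  est5 <- make_est(paste0("g", 1:5), c(10, 20, 30, 40, 50), rep(0.2, 5))
  q_spec <- dimension_spec("grad", "ordered", paste0("g", 1:5))
  sii_log <- slope_index(est5, q_spec, scale = "logit")
  expect_true(abs(sii_log$value) <= 100)
  expect_gt(sii_log$value, 0)
  rii_log <- relative_index(est5, q_spec, scale = "logit")
  expect_gt(rii_log$value, 1)
})

test_that("ratio degenerates gracefully when the low subgroup is zero", {
  est <- make_est(c("low", "mid", "high"), c(0, 10, 30), rep(1 / 3, 3),
                  half_width = 0)
  r <- inequality_ratio(est, ord_spec3)
  expect_false(r$applicable)
  expect_true(is.na(r$value))
})
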