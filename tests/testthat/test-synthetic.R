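test_that("quintile assignment: equal weights, cumulative walk, permutation", {
  # ten equal-weight scores -> two per quintile
  q <- quintile_assign(1:10)
  expect_equal(as.character(q),
               rep(paste0("Q", 1:5), each = 2))

  # a dominant household (60% of weight, lowest score) is labelled by the
  # quintile containing the midpoint of its weight interval (0.30 -> Q2);
  # verified against a brute-force cumulative-weight walk
  scores <- 1:6
  w <- c(60, 8, 8, 8, 8, 8)
  q <- quintile_assign(scores, w)
  walk <- function(scores, w) {
    ord <- order(scores)
    cumw <- cumsum(w[ord])
    mid <- (cumw - w[ord] / 2) / sum(w)
    # right-closed quintile intervals ((j-1)/5, j/5]
    lab <- findInterval(mid, seq(0, 1, by = 0.2), left.open = TRUE)
    out <- integer(length(w))
    out[ord] <- lab
    paste0("Q", out)
  }
  expect_equal(as.character(q), walk(scores, w))
  expect_equal(as.character(q)[1], "Q2")

  # permuting the input leaves membership (per score) unchanged
  perm <- c(3, 1, 4, 6, 2, 5)
  q2 <- quintile_assign(scores[perm], w[perm])
  expect_equal(as.character(q2), as.character(q)[perm])

  expect_error(quintile_assign(c(1, 1, 1, 2, 2), rep(1, 5)), "distinct")
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(seed = 99, clusters_per_region = 5)
  a <- generate_population(cfg, 2011)
  b <- generate_population(cfg, 2011)
  expect_identical(a, b)
  c <- generate_population(cfg, 2016)
  expect_false(identical(a$outcome, c$outcome))
})

test_that("record invariants: weights, quintile balance, cluster mapping", {
  rec <- generate_population(synthetic_config(seed = 3), 2019)
  expect_true(all(rec$sampling_weight > 0))
  expect_equal(mean(rec$sampling_weight), 1, tolerance = 1e-10)

  sh <- tapply(rec$sampling_weight, rec$wealth_quintile, sum) /
    sum(rec$sampling_weight)
  expect_true(all(abs(sh - 0.2) < 0.01))

  map <- unique(rec[, c("cluster_id", "region", "residence")])
  expect_equal(nrow(map), length(unique(rec$cluster_id)))
})

test_that("zero-effect null config gives flat subgroup coverage", {
  cfg <- null_config(seed = 5, clusters_per_region = 40)
  rec <- generate_population(cfg, 2000)
  expect_gt(nrow(rec), 3000)
  for (d in c("wealth_quintile", "residence", "sex")) {
    cov <- tapply(rec$sampling_weight * rec$outcome, rec[[d]], sum) /
      tapply(rec$sampling_weight, rec[[d]], sum)
    expect_lt(diff(range(cov)), 0.06)
  }
})

test_that("wealth gradient matches the closed-form marginalization oracle", {
  cfg <- null_config(seed = 11, clusters_per_region = 110)
  cfg$beta_wealth <- 0.35
  rec <- generate_population(cfg, 2000)
  expect_gt(nrow(rec), 8000)
  p <- tapply(rec$sampling_weight * rec$outcome, rec$wealth_quintile, sum) /
    tapply(rec$sampling_weight, rec$wealth_quintile, sum)
  emp_gap <- qlogis(p[["Q5"]]) - qlogis(p[["Q1"]])
  # oracle: average the per-stratum inverse-logit probabilities over the
  # realized covariate table (only the quintile enters the logit here)
  lp <- -0.7 + 0.35 * (as.integer(factor(rec$wealth_quintile)) - 1)
  p_oracle <- tapply(rec$sampling_weight * plogis(lp), rec$wealth_quintile,
                     sum) /
    tapply(rec$sampling_weight, rec$wealth_quintile, sum)
  oracle_gap <- qlogis(p_oracle[["Q5"]]) - qlogis(p_oracle[["Q1"]])
  expect_equal(oracle_gap, 1.4, tolerance = 1e-10)
  expect_equal(unname(emp_gap), unname(oracle_gap), tolerance = 0.15)
})

test_that("empirical ICC increases with the cluster random-intercept sd", {
  mean_icc <- vapply(c(0.2, 0.8, 1.6), function(s) {
    iccs <- vapply(1:3, function(r) {
      cfg <- null_config(seed = 100 * r, clusters_per_region = 25)
      cfg$cluster_sd <- s
      rec <- generate_population(cfg, 2000)
      icc_anova(rec$outcome, rec$cluster_id)
    }, numeric(1))
    mean(iccs)
  }, numeric(1))
  expect_true(all(diff(mean_icc) > 0))
})

test_that("pro-rich gradient: Q5 above Q1 in nearly all seeds", {
  hits <- vapply(1:20, function(s) {
    rec <- generate_population(synthetic_config(seed = 1000 + s), 2019)
    p <- tapply(rec$sampling_weight * rec$outcome, rec$wealth_quintile,
                sum) /
      tapply(rec$sampling_weight, rec$wealth_quintile, sum)
    p[["Q5"]] > p[["Q1"]]
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("children CSV round-trips with the fixed column order", {
  rec <- generate_population(synthetic_config(seed = 8,
                                              clusters_per_region = 4), 2019)
  path <- withr::local_tempfile(fileext = ".csv")
  write_children_csv(rec, path)
  back <- read_children_csv(path)
  expect_equal(names(back)[1:2], c("child_id", "survey_year"))
  expect_equal(back$outcome, rec$outcome)
  expect_equal(back$sampling_weight, rec$sampling_weight, tolerance = 1e-12)
})
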