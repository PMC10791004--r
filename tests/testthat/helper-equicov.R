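# Shared fixtures and independent oracles for the test suite.

# Minimal hand-built child records: one row per child, explicit weights and
# cluster structure, so expected values can be computed by hand.
tiny_records <- function(outcomes, weights = rep(1, length(outcomes)),
                         clusters = rep("c1", length(outcomes)),
                         year = 2019) {
  n <- length(outcomes)
  tibble::tibble(
    child_id = paste0("k", seq_len(n)),
    survey_year = year,
    region = "R01",
    residence = "rural",
    cluster_id = clusters,
    household_id = paste0("h", seq_len(n)),
    sampling_weight = weights,
    outcome = outcomes
  )
}

# A flat (no true effects, no clustering) generator configuration.
null_config <- function(seed = 1, clusters_per_region = 20,
                        base = -0.7, n_regions = 6) {
  synthetic_config(
    n_regions = n_regions, clusters_per_region = clusters_per_region,
    region_log_odds = rep(base, n_regions),
    beta_wealth = 0, beta_education = 0, beta_urban = 0, beta_sex = 0,
    beta_age = 0, beta_anc = 0, beta_facility_delivery = 0,
    beta_birth_order = 0, cluster_sd = 0,
    urban_fraction_by_region = rep(0.2, n_regions),
    seed = seed
  )
}

# One-way ANOVA estimator of the intraclass correlation (independent of the
# model-based ICC in the package).
icc_anova <- function(y, g) {
  g <- factor(g)
  n_j <- as.numeric(table(g))
  N <- sum(n_j)
  J <- length(n_j)
  fit <- stats::aov(y ~ g)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]
  msw <- ms[2]
  n0 <- (N - sum(n_j^2) / N) / (J - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

# Gauss-Hermite nodes/weights via Golub-Welsch (weight function exp(-x^2)).
gh_nodes <- function(k) {
  i <- seq_len(k - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ])^2 * sqrt(pi))
}

# Brute-force marginal log-likelihood of a random-intercept logistic model:
# per cluster, integrate the conditional Bernoulli likelihood over the
# Normal(0, sigma^2) intercept with plain (non-adaptive) Gauss-Hermite
# quadrature. Independent of lme4's adaptive scheme.
marginal_loglik_gh <- function(y, eta, cluster, sigma, k = 201) {
  nd <- gh_nodes(k)
  ll <- 0
  for (idx in split(seq_along(y), cluster)) {
    contrib <- vapply(seq_len(k), function(j) {
      b <- sqrt(2) * sigma * nd$x[j]
      p <- stats::plogis(eta[idx] + b)
      exp(sum(stats::dbinom(y[idx], 1, p, log = TRUE)))
    }, numeric(1))
    ll <- ll + log(sum(nd$w * contrib) / sqrt(pi))
  }
  ll
}

# Brute-force weighted-least-squares solve of the ridit regression via the
# normal equations (oracle for slope_index / relative_index).
wls_oracle <- function(shares, estimates) {
  sh <- shares / sum(shares)
  x <- cumsum(sh) - sh / 2
  X <- cbind(1, x)
  beta <- solve(t(X) %*% diag(sh) %*% X, t(X) %*% diag(sh) %*% estimates)
  list(v0 = beta[1], v1 = beta[1] + beta[2], slope = beta[2])
}

paper_estimates <- equicov::edhs_dpt3_estimates()
paper_national <- equicov::edhs_dpt3_national()
# the education-2000 RII degeneracy warning is expected and tested for
paper_measures <- suppressWarnings(
  equicov::summary_measures(paper_estimates, paper_national))

measure_cell <- function(tab, dimension, measure, year, col = "value") {
  tab[[col]][tab$dimension == dimension & tab$measure == measure &
               tab$year == year]
}
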