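#' Specify the two-level determinants model
#'
#' Children are nested in communities (PSUs/clusters). Community-level
#' terms (survey year, region, residence) and individual-level terms
#' (wealth quintile, maternal education, maternal age, sex, birth order,
#' antenatal care, place of delivery) enter as fixed effects; the community
#' contributes a random intercept.
#'
#' @param outcome Binary outcome column.
#' @param community_terms,individual_terms Fixed-effect column names.
#' @param grouping Cluster identifier column (the "community").
#' @param reference_levels Named list mapping categorical terms to their
#'   reference label.
#' @return List of class `equicov_ml_spec`.
#' @export
multilevel_spec <- function(outcome = "outcome",
                            community_terms = c("survey_year", "region",
                                                "residence"),
                            individual_terms = c("wealth_quintile",
                                                 "maternal_education",
                                                 "maternal_age", "sex",
                                                 "birth_order", "anc_visits",
                                                 "facility_delivery"),
                            grouping = "cluster_id",
                            reference_levels = list()) {
  structure(
    list(outcome = outcome, community_terms = community_terms,
         individual_terms = individual_terms, grouping = grouping,
         reference_levels = reference_levels),
    class = "equicov_ml_spec"
  )
}

#' Fit the two-level random-intercept logistic model
#'
#' Maximizes the random-intercept binomial likelihood with the Laplace
#' approximation (`lme4::glmer`, `nAGQ = 1` by default; raise `nAGQ` for
#' adaptive Gauss-Hermite quadrature). Reports odds ratios with Wald 95%
#' CIs, the random-intercept variance, and the latent-scale intraclass
#' correlation `var / (var + pi^2/3)`. With `grouping = NULL` an ordinary
#' logistic model is fitted instead.
#'
#' Degenerate designs are rejected up front: constant or aliased fixed
#' -effect columns raise an error naming the offending term, and complete
#' separation is reported when detected.
#'
#' @param records Child-record tibble.
#' @param spec A [multilevel_spec()].
#' @param weights Optional column name of sampling weights for a weighted
#'   pseudo-likelihood fit (default: unweighted).
#' @param nAGQ Number of adaptive quadrature points (1 = Laplace).
#' @return `equicov_mlfit`: list with `fixed_effects` tibble (term, level,
#'   estimate (log-odds), `or`, `ci_low`, `ci_high`, `p_value`),
#'   `random_intercept_variance`, `icc`, `converged`, `n_obs`, `n_groups`,
#'   `loglik` and the underlying `fit`.
#' @export
fit_multilevel <- function(records, spec = multilevel_spec(),
                           weights = NULL, nAGQ = 1) {
  terms <- c(spec$community_terms, spec$individual_terms)
  missing <- setdiff(c(spec$outcome, terms,
                       if (!is.null(spec$grouping)) spec$grouping),
                     names(records))
  if (length(missing)) {
    abort(paste("records are missing columns:",
                paste(missing, collapse = ", ")))
  }
  dat <- as.data.frame(records)
  y <- dat[[spec$outcome]]
  if (!all(y %in% c(0, 1))) abort("outcome must be binary 0/1")

  for (tm in terms) {
    if (is.character(dat[[tm]]) || is.factor(dat[[tm]]) ||
        tm == "survey_year") {
      dat[[tm]] <- factor(dat[[tm]])
      ref <- spec$reference_levels[[tm]]
      if (!is.null(ref)) {
        if (!ref %in% levels(dat[[tm]])) {
          abort(paste0("reference level '", ref, "' not found in '", tm, "'"))
        }
        dat[[tm]] <- relevel(dat[[tm]], ref = ref)
      }
    }
  }

  rhs <- paste(terms, collapse = " + ")
  X <- stats::model.matrix(as.formula(paste("~", rhs)), dat)
  const_cols <- apply(X[, -1, drop = FALSE], 2, function(col)
    length(unique(col)) == 1)
  if (any(const_cols)) {
    abort(paste("constant fixed-effect column(s):",
                paste(names(const_cols)[const_cols], collapse = ", ")))
  }
  qr_rank <- qr(X)$rank
  if (qr_rank < ncol(X)) {
    abort("fixed-effect design is rank deficient (aliased terms)")
  }

  w <- if (!is.null(weights)) dat[[weights]] else NULL
  if (is.null(spec$grouping)) {
    fit <- glm(as.formula(paste(spec$outcome, "~", rhs)),
               family = binomial(), data = dat, weights = w)
    beta <- coef(fit)
    V <- vcov(fit)
    var_ri <- 0
    converged <- fit$converged
    n_groups <- NA_integer_
    ll <- as.numeric(logLik(fit))
  } else {
    if (length(unique(dat[[spec$grouping]])) < 2) {
      abort("need at least 2 clusters for a random intercept")
    }
    form <- as.formula(paste(spec$outcome, "~", rhs,
                             "+ (1 |", spec$grouping, ")"))
    fit <- lme4::glmer(form, data = dat, family = binomial(),
                       weights = w, nAGQ = nAGQ,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa",
                         optCtrl = list(maxfun = 1e5),
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    var_ri <- as.numeric(lme4::VarCorr(fit)[[spec$grouping]][1])
    converged <- length(fit@optinfo$conv$lme4$messages) == 0
    n_groups <- lme4::ngrps(fit)[[spec$grouping]]
    ll <- as.numeric(logLik(fit))
  }
  if (!converged) warn("model did not converge cleanly; inspect $fit")
  se <- sqrt(diag(V))
  if (any(abs(beta[-1]) > 10)) {
    warn(paste("possible complete separation; extreme coefficient(s):",
               paste(names(beta[-1])[abs(beta[-1]) > 10], collapse = ", ")))
  }
  z <- qnorm(0.975)
  term_of <- attr(X, "assign")
  term_labels <- c("(Intercept)", terms)[term_of + 1]
  fx <- tibble::tibble(
    term = term_labels,
    coefficient = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * se),
    ci_high = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se))
  )
  structure(
    list(
      fixed_effects = fx,
      random_intercept_variance = var_ri,
      icc = var_ri / (var_ri + pi^2 / 3),
      converged = converged,
      n_obs = nrow(dat),
      n_groups = n_groups,
      loglik = ll,
      estimation = if (is.null(spec$grouping)) "glm"
                   else if (nAGQ == 1) "Laplace"
                   else paste0("adaptive GH (", nAGQ, " points)"),
      fit = fit
    ),
    class = "equicov_mlfit"
  )
}

#' @export
print.equicov_mlfit <- function(x, ...) {
  cat("<equicov_mlfit> two-level random-intercept logistic (",
      x$estimation, ")\n", sep = "")
  cat("  n = ", x$n_obs, " children in ", x$n_groups, " communities; ",
      "converged: ", x$converged, "\n", sep = "")
  cat(sprintf("  random-intercept variance = %.4f  (ICC = %.3f)\n",
              x$random_intercept_variance, x$icc))
  fx <- x$fixed_effects[x$fixed_effects$term != "(Intercept)", ]
  cat(sprintf("  %-28s OR %6.2f  (%5.2f, %5.2f)\n",
              fx$coefficient, fx$or, fx$ci_low, fx$ci_high), sep = "")
  invisible(x)
}

#' Write the odds-ratio table of a multilevel fit as CSV
#'
#' @param fit An `equicov_mlfit`.
#' @param path Output CSV (term, level, OR, ci_low, ci_high).
#' @param meta_path Optional JSON path for model metadata (convergence,
#'   ICC, sizes).
#' @return `path`, invisibly.
#' @export
write_multilevel_csv <- function(fit, path, meta_path = NULL) {
  fx <- fit$fixed_effects
  out <- data.frame(
    term = fx$term,
    level = sub("^.*?\\((.*)\\)$", "\\1",
                ifelse(fx$coefficient == "(Intercept)", "(Intercept)",
                       substring(fx$coefficient, nchar(fx$term) + 1))),
    or = fx$or, ci_low = fx$ci_low, ci_high = fx$ci_high
  )
  out$level[out$level == ""] <- "(linear)"
  write.csv(out, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(converged = fit$converged, icc = fit$icc,
           random_intercept_variance = fit$random_intercept_variance,
           n_obs = fit$n_obs, n_groups = fit$n_groups,
           estimation = fit$estimation),
      meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
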