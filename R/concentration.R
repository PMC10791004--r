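# Weighted fractional ranks in ascending order of a ranking variable; tied
# blocks share the mean rank of their block: R_i = (cumw_before + w_block/2)/W
weighted_fractional_rank <- function(ranking, weights) {
  ord <- order(ranking)
  w <- weights[ord]
  r_sorted <- ranking[ord]
  blocks <- cumsum(!duplicated(r_sorted))
  w_block <- tapply(w, blocks, sum)
  cum_before <- cumsum(c(0, w_block[-length(w_block)]))
  rank_block <- (cum_before + w_block / 2) / sum(w)
  out <- numeric(length(ranking))
  out[ord] <- rank_block[blocks]
  out
}

#' Concentration index of a health variable over a socioeconomic ranking
#'
#' `C = 2 * cov_w(y, R) / mu`, where `R` is the weighted fractional rank in
#' the socioeconomic distribution (ties share their block's mean rank) and
#' the weighted covariance uses the total-weight normalization. Positive
#' values mean the outcome is concentrated among the better-off (pro-rich).
#'
#' @param y Health variable (e.g. 0/1 immunization status).
#' @param ranking Socioeconomic score used for ranking (e.g. latent asset
#'   score, or quintile when no continuous score is available).
#' @param weights Positive sampling weights (default equal).
#' @param small_sample_correction Multiply by `n/(n-1)` (off by default).
#' @return The index, in `[-1, 1]` for non-negative `y`.
#' @export
concentration_index <- function(y, ranking, weights = NULL,
                                small_sample_correction = FALSE) {
  n <- length(y)
  if (n == 0) abort("no observations")
  if (is.null(weights)) weights <- rep(1, n)
  mu <- weighted.mean(y, weights)
  if (mu <= 0) abort("mean outcome must be positive")
  r <- weighted_fractional_rank(ranking, weights)
  w <- weights / sum(weights)
  cov_w <- sum(w * (y - mu) * (r - sum(w * r)))
  ci <- 2 * cov_w / mu
  if (small_sample_correction) ci <- ci * n / (n - 1)
  ci
}

#' Concentration curve
#'
#' Records are sorted by the socioeconomic ranking variable (tied values
#' aggregated into one step) and the cumulative weighted population share is
#' plotted against the cumulative weighted outcome share. A curve below the
#' diagonal indicates a pro-rich distribution. The `index_value` attached to
#' the curve is twice the (weighted trapezoid) area between the diagonal and
#' the curve, which agrees with [concentration_index()] up to O(1/n).
#'
#' @inheritParams concentration_index
#' @param ranking_variable Name recorded on the curve object.
#' @return An `equicov_curve`: tibble of `(cum_population, cum_outcome)`
#'   points (starting at (0,0), ending at (1,1)) with attributes
#'   `index_value` and `ranking_variable`.
#' @export
concentration_curve <- function(y, ranking, weights = NULL,
                                ranking_variable = "ranking") {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(y * weights) <= 0) abort("total outcome must be positive")
  ord <- order(ranking)
  w <- weights[ord]
  yo <- y[ord]
  blocks <- cumsum(!duplicated(ranking[ord]))
  w_b <- as.numeric(tapply(w, blocks, sum))
  t_b <- as.numeric(tapply(w * yo, blocks, sum))
  pts <- tibble::tibble(
    cum_population = c(0, cumsum(w_b) / sum(w_b)),
    cum_outcome = c(0, cumsum(t_b) / sum(t_b))
  )
  auc <- sum(diff(pts$cum_population) *
               (utils::head(pts$cum_outcome, -1) +
                  utils::tail(pts$cum_outcome, -1)) / 2)
  structure(pts,
            class = c("equicov_curve", class(pts)),
            index_value = 1 - 2 * auc,
            ranking_variable = ranking_variable)
}

#' @export
print.equicov_curve <- function(x, ...) {
  cat("<equicov_curve> ", nrow(x) - 1, " steps, ranked by ",
      attr(x, "ranking_variable"), "\n", sep = "")
  cat("  area-based concentration index: ",
      format(attr(x, "index_value"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Weighted Gini index via the Lorenz curve
#'
#' Units are sorted ascending by value; the Gini is the ratio of the area
#' between the equality line and the Lorenz curve to the total area under
#' the equality line, `G = A / (A + B)`, computed by trapezoid integration.
#'
#' @param values Non-negative quantities (e.g. coverage, income).
#' @param weights Positive weights (default equal).
#' @return Gini index in `[0, 1]`.
#' @export
gini_index <- function(values, weights = NULL) {
  if (any(values < 0)) abort("values must be non-negative")
  if (sum(values) <= 0) abort("total value must be positive")
  if (is.null(weights)) weights <- rep(1, length(values))
  ord <- order(values)
  w <- weights[ord]
  v <- values[ord]
  p <- c(0, cumsum(w) / sum(w))
  L <- c(0, cumsum(w * v) / sum(w * v))
  auc <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  1 - 2 * auc
}

#' Lorenz curve points
#'
#' @inheritParams gini_index
#' @return Tibble of `(cum_population, cum_value)` points with the Gini as
#'   attribute `index_value`.
#' @export
lorenz_curve <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  ord <- order(values)
  w <- weights[ord]
  v <- values[ord]
  pts <- tibble::tibble(
    cum_population = c(0, cumsum(w) / sum(w)),
    cum_outcome = c(0, cumsum(w * v) / sum(w * v))
  )
  structure(pts, class = c("equicov_curve", class(pts)),
            index_value = gini_index(values, weights),
            ranking_variable = "value")
}

#' Write curve points to CSV (for external plotting)
#'
#' @param curve An `equicov_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  df$index_value <- attr(curve, "index_value")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a concentration or Lorenz curve against the equality line
#'
#' @param curve An `equicov_curve`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$cum_population,
                               y = .data$cum_outcome)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative population share (ranked)",
      y = "Cumulative outcome share",
      subtitle = sprintf("index = %.3f", attr(curve, "index_value"))
    ) +
    ggplot2::theme_minimal()
}
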