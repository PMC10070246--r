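#' Posterior-predictive distance sample
#'
#' Draws parameters from the fitted ensemble (proportionally to the
#' importance weights), generates one matched synthetic dataset per draw,
#' computes its windowed autocorrelation exactly as for the data, and
#' returns the distances to the observed autocorrelation. The distribution
#' of these distances measures the goodness of fit of the model.
#'
#' @param post a `posterior_ensemble` from [abc_fit()].
#' @param ac_data observed `corr_function`.
#' @param stats_ `data_stats` of the observed counts.
#' @param n number of realizations (default 1000).
#' @return Numeric vector of `n` distances.
#' @export
posterior_predictive_distances <- function(post, ac_data, stats_, n = 1000) {
  stopifnot(inherits(post, "posterior_ensemble"))
  cfg <- post$cfg
  max_lag_bins <- as.integer(cfg$t_m_ms / stats_$bin_ms)
  idx <- sample.int(nrow(post$samples), n, replace = TRUE,
                    prob = post$weights)
  obs <- ac_data$values[seq_len(max_lag_bins + 1L)]
  vapply(idx, function(i) {
    synth <- abc_synth_ac(post$samples[i, ], post$model, stats_,
                          max_lag_bins)
    if (is.null(synth)) return(NA_real_)
    ac_distance(obs, synth, t_m_ms = cfg$t_m_ms, bin_ms = stats_$bin_ms,
                excluded_lags_ms = cfg$excluded_lags_ms,
                fit_zero_lag = cfg$fit_zero_lag)
  }, numeric(1))
}

#' Compare two generative models by the acceptance-rate Bayes factor
#'
#' The acceptance rate of a model at error threshold eps equals the CDF of
#' its posterior-predictive distance distribution at eps, so the ratio
#' CDF_B(eps)/CDF_A(eps) approximates the Bayes factor B over A. The
#' comparison first gates on a two-sided Wilcoxon rank-sum test between the
#' two distance samples; if they are not significantly different the data
#' are insufficient and the verdict is inconclusive. Otherwise the Bayes
#' factor is evaluated at every distinct pooled distance below the larger of
#' the two medians; the model with smaller distances wins only if its Bayes
#' factor exceeds 1 across that whole admissible range (crossing CDFs give
#' an inconclusive verdict).
#'
#' @param dist_a,dist_b distance samples for models A and B (e.g. one- and
#'   two-timescale fits).
#' @param labels model names (default "M1", "M2").
#' @param gate_level significance level of the rank-sum gate (default 0.05).
#' @param min_tail thresholds enter the BF check only once at least this
#'   many pooled predictive samples lie below them; below that the empirical
#'   CDF ratio has no resolution and a single extreme draw would decide the
#'   verdict (default 5).
#' @return A `model_comparison`: verdict (one of the labels or
#'   "inconclusive"), gate p-value, medians and the BF(eps) curve of model B
#'   over model A.
#' @export
compare_models <- function(dist_a, dist_b, labels = c("M1", "M2"),
                           gate_level = 0.05, min_tail = 5) {
  dist_a <- dist_a[is.finite(dist_a)]; dist_b <- dist_b[is.finite(dist_b)]
  stopifnot(length(dist_a) > 0, length(dist_b) > 0)
  gate <- stats::wilcox.test(dist_a, dist_b, exact = FALSE)
  med_a <- stats::median(dist_a); med_b <- stats::median(dist_b)
  eps_max <- max(med_a, med_b)
  grid <- sort(unique(c(dist_a, dist_b)))
  grid <- grid[grid <= eps_max]
  cdf_a <- stats::ecdf(dist_a)(grid)
  cdf_b <- stats::ecdf(dist_b)(grid)
  pooled_n <- cdf_a * length(dist_a) + cdf_b * length(dist_b)
  bf <- ifelse(cdf_a == 0, ifelse(cdf_b > 0, Inf, NA_real_), cdf_b / cdf_a)
  bf[pooled_n < min_tail] <- NA_real_
  defined <- !is.na(bf)
  verdict <- "inconclusive"
  if (gate$p.value < gate_level && any(defined)) {
    if (med_b < med_a && all(bf[defined] > 1)) verdict <- labels[2]
    else if (med_a < med_b && all(bf[defined] < 1)) verdict <- labels[1]
  }
  structure(list(verdict = verdict, gate_p = gate$p.value,
                 medians = stats::setNames(c(med_a, med_b), labels),
                 eps_grid = grid, bf_curve = bf, labels = labels,
                 gate_level = gate_level),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  fin <- x$bf_curve[is.finite(x$bf_curve)]
  cat(sprintf("<model_comparison> verdict: %s (gate p = %.3g, BF[%s/%s] in [%.3g, %.3g])\n",
              x$verdict, x$gate_p, x$labels[2], x$labels[1],
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' Fit both candidate models and select between them
#'
#' Convenience wrapper: fits the one- and two-timescale models with
#' [abc_fit()], draws posterior-predictive distances for each and runs
#' [compare_models()].
#'
#' @param ac_data observed `corr_function`.
#' @param stats_ `data_stats`.
#' @param cfg an [abc_config()].
#' @param n_pred posterior-predictive realizations per model.
#' @return List with `fit_M1`, `fit_M2`, `comparison`.
#' @export
select_timescale_model <- function(ac_data, stats_, cfg = abc_config(),
                                   n_pred = 1000) {
  fit1 <- abc_fit(ac_data, stats_, "M1", cfg)
  fit2 <- abc_fit(ac_data, stats_, "M2", cfg)
  d1 <- posterior_predictive_distances(fit1, ac_data, stats_, n_pred)
  d2 <- posterior_predictive_distances(fit2, ac_data, stats_, n_pred)
  list(fit_M1 = fit1, fit_M2 = fit2,
       comparison = compare_models(d1, d2, c("M1", "M2")))
}
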