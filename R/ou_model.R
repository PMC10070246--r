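#' Parameters of the OU-mixture generative model
#'
#' The doubly stochastic generative model for binned spike counts: the latent
#' rate is a linear mixture of independent Ornstein-Uhlenbeck processes,
#' A_OU(t) = sum_k sqrt(c_k) A_{tau_k}(t) with sum(c_k) = 1, and counts are
#' drawn from a gamma law whose variance/mean ratio is the dispersion `alpha`
#' (alpha = 1 recovers Poisson-like dispersion). Timescales are stored in
#' ascending order for identifiability.
#'
#' @param tau ms; one to three timescales.
#' @param c_k mixture weights in `[0, 1]` summing to 1 (recycled to 1 for a
#'   single timescale).
#' @param alpha dispersion (variance over mean of counts), > 0.
#' @return An `ou_params` object.
#' @export
ou_params <- function(tau, c_k = rep(1 / length(tau), length(tau)),
                      alpha = 1) {
  stopifnot(length(tau) >= 1, length(tau) <= 3, all(is.finite(tau)),
            all(tau > 0), length(c_k) == length(tau), all(c_k >= 0),
            abs(sum(c_k) - 1) < 1e-8, is.finite(alpha), alpha > 0)
  o <- order(tau)
  structure(list(tau = tau[o], c_k = c_k[o], alpha = alpha,
                 n_timescales = length(tau)), class = "ou_params")
}

#' Summary statistics of a binned-count dataset
#'
#' The statistics the generative model is matched to: number of
#' trials/windows, window and bin durations, and the mean and variance of
#' the spike counts per bin. Matching these makes the windowed
#' autocorrelation of synthetic data subject to the same statistical bias as
#' the data it is fitted to.
#'
#' @param n_trials number of windows.
#' @param window_ms window duration (ms).
#' @param bin_ms bin size (ms).
#' @param count_mean,count_variance per-bin spike-count moments.
#' @return A `data_stats` object.
#' @export
data_stats <- function(n_trials, window_ms, bin_ms = 2, count_mean,
                       count_variance) {
  stopifnot(n_trials >= 1, window_ms > 0, bin_ms > 0,
            window_ms %% bin_ms == 0, count_variance >= 0)
  structure(list(n_trials = as.integer(n_trials), window_ms = window_ms,
                 bin_ms = bin_ms, count_mean = count_mean,
                 count_variance = count_variance), class = "data_stats")
}

#' Compute `data_stats` from binned counts
#' @param bc a `binned_counts` object.
#' @return A `data_stats` object.
#' @export
data_stats_from_counts <- function(bc) {
  data_stats(nrow(bc$counts), bc$window_ms, bc$bin_ms,
             mean(bc$counts), stats::var(as.vector(bc$counts)))
}

#' Simulate latent OU-mixture rate traces
#'
#' Each component is simulated with its exact discretization: a stationary
#' AR(1) with coefficient exp(-bin/tau_k) and unit stationary variance,
#' started from the stationary law. Components are mixed with amplitudes
#' sqrt(c_k), so the latent autocorrelation is sum_k c_k exp(-t/tau_k) and
#' the lag-0 variance is 1.
#'
#' @param params an `ou_params` object.
#' @param n_trials number of independent traces.
#' @param n_bins bins per trace.
#' @param bin_ms bin size in ms.
#' @return Matrix (n_trials x n_bins) of latent amplitudes.
#' @export
simulate_ou_mixture <- function(params, n_trials, n_bins, bin_ms = 2) {
  stopifnot(inherits(params, "ou_params"))
  A <- matrix(0, n_trials, n_bins)
  for (k in seq_along(params$tau)) {
    if (params$c_k[k] == 0) next
    phi <- exp(-bin_ms / params$tau[k])
    innov_sd <- sqrt(1 - phi^2)
    x <- matrix(0, n_trials, n_bins)
    x[, 1] <- stats::rnorm(n_trials)            # stationary start, unit var
    for (i in 2:n_bins)
      x[, i] <- phi * x[, i - 1] + innov_sd * stats::rnorm(n_trials)
    A <- A + sqrt(params$c_k[k]) * x
  }
  A
}

#' Sample dispersed spike counts from latent rates
#'
#' Affinely rescales the unit-variance latent traces so that the counts
#' match the target per-bin mean and variance in expectation, then draws
#' each bin's count from a gamma law with mean lambda and variance
#' alpha * lambda (shape lambda/alpha, scale alpha). Negative instantaneous
#' rates are clipped to zero before sampling. The total count variance
#' decomposes as alpha * mean (point-process part) + rate-driven variance,
#' so the target variance must exceed alpha * mean.
#'
#' @param rates latent trace matrix from [simulate_ou_mixture()].
#' @param stats_ a `data_stats` object with the target moments.
#' @param alpha dispersion parameter.
#' @return Matrix of counts, same shape as `rates`.
#' @export
sample_counts <- function(rates, stats_, alpha) {
  stopifnot(inherits(stats_, "data_stats"), alpha > 0)
  rate_var <- stats_$count_variance - alpha * stats_$count_mean
  if (rate_var < 0)
    stop(sprintf(paste0("infeasible targets: count variance %.4g is below ",
                        "alpha * mean = %.4g; no rate fluctuation can match"),
                 stats_$count_variance, alpha * stats_$count_mean))
  lambda <- pmax(stats_$count_mean + sqrt(rate_var) * rates, 0)
  cnt <- matrix(0, nrow(rates), ncol(rates))
  pos <- lambda > 0
  cnt[pos] <- stats::rgamma(sum(pos), shape = lambda[pos] / alpha,
                            scale = alpha)
  cnt
}

#' Generate a synthetic dataset matched to observed count statistics
#'
#' Composition of [simulate_ou_mixture()] and [sample_counts()]: independent
#' trials with the same number of windows, window duration, bin size, count
#' mean and count variance as the data. Returned as a `binned_counts` object
#' so the downstream correlation pipeline treats synthetic and real data
#' identically (and both incur the same finite-window estimation bias).
#'
#' @param params an `ou_params` object.
#' @param stats_ a `data_stats` object.
#' @param condition label attached to all windows.
#' @return A `binned_counts` object.
#' @export
generate_matched_dataset <- function(params, stats_, condition = "synthetic") {
  nb <- as.integer(stats_$window_ms / stats_$bin_ms)
  A <- simulate_ou_mixture(params, stats_$n_trials, nb, stats_$bin_ms)
  cnt <- sample_counts(A, stats_, params$alpha)
  structure(list(counts = cnt, bin_ms = stats_$bin_ms,
                 window_ms = stats_$window_ms,
                 condition = rep(condition, stats_$n_trials),
                 trial = seq_len(stats_$n_trials),
                 dropped = data.frame(trial = integer(0),
                                      reason = character(0))),
            class = "binned_counts")
}

#' Closed-form latent autocorrelation of an OU mixture
#' @param params an `ou_params` object.
#' @param t_ms lags in ms.
#' @return sum_k c_k exp(-t/tau_k).
#' @export
ou_mixture_ac <- function(params, t_ms) {
  rowSums(vapply(seq_along(params$tau),
                 function(k) params$c_k[k] * exp(-t_ms / params$tau[k]),
                 numeric(length(t_ms))))
}
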