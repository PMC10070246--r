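# Shared helpers for the test suite. All fixtures are generated in code.

# Observed correlation function for ABC tests: window-averaged windowed AC
# of one matched synthetic dataset drawn from `params`.
observed_ac <- function(params, stats_, max_lag_bins = 50L) {
  bc <- generate_matched_dataset(params, stats_)
  acm <- multitau:::windowed_ac_matrix(bc$counts, max_lag_bins)
  ok <- stats::complete.cases(acm)
  corr_function((0:max_lag_bins) * stats_$bin_ms,
                colMeans(acm[ok, , drop = FALSE]), "auto",
                sum(ok), stats_$bin_ms)
}

# A fake posterior ensemble around known samples (for MAP/summary tests).
fake_ensemble <- function(samples, weights = NULL, model = "M2",
                          box = NULL) {
  if (is.null(weights)) weights <- rep(1 / nrow(samples), nrow(samples))
  if (is.null(box)) box <- abc_prior_box(model)
  structure(list(samples = samples, weights = weights,
                 distances = rep(0, nrow(samples)),
                 eps_history = 0.1, accR_history = 1, model = model,
                 prior_box = box[, colnames(samples), drop = FALSE],
                 cfg = abc_config(), stop_reason = "test"),
            class = "posterior_ensemble")
}

abc_prior_box <- multitau:::abc_prior_box

# Tiny spike-event session built by hand for binning tests.
toy_events <- function() {
  list(events = data.frame(trial = c(1L, 1L, 1L, 2L, 2L),
                           channel = c(1L, 2L, 2L, 1L, 1L),
                           time_ms = c(1, 3, 3, 0.5, 5.5),
                           condition = "a"),
       trials = data.frame(trial = 1:2, duration_ms = c(6, 6),
                           condition = "a"))
}
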