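test_that("OU mixture parameters are validated and ordered", {
  p <- ou_params(c(100, 5), c(0.7, 0.3), 1.1)
  expect_equal(p$tau, c(5, 100))                    # ascending
  expect_equal(p$c_k, c(0.3, 0.7))                  # weights follow the sort
  expect_error(ou_params(c(5, 100), c(0.5, 0.4)), "sum")
  expect_error(ou_params(-5), "tau")
})

test_that("latent OU mixture has the closed-form autocorrelation and unit variance", {
  set.seed(10)
  lags <- 0:40
  # single timescale: AC = exp(-t / tau)
  A1 <- simulate_ou_mixture(ou_params(20), n_trials = 400, n_bins = 300,
                            bin_ms = 2)
  emp1 <- sapply(lags, function(l)
    mean(A1[, 1:(300 - l)] * A1[, (l + 1):300]))
  expect_lt(max(abs(emp1 - exp(-lags * 2 / 20))), 0.03)
  expect_equal(mean(A1^2), 1, tolerance = 0.02)     # unit stationary variance

  # two timescales: AC = 0.5 exp(-t/5) + 0.5 exp(-t/100)
  p <- ou_params(c(5, 100), c(0.5, 0.5), 1)
  A2 <- simulate_ou_mixture(p, 400, 300, 2)
  emp2 <- sapply(lags, function(l)
    mean(A2[, 1:(300 - l)] * A2[, (l + 1):300]))
  expect_lt(max(abs(emp2 - ou_mixture_ac(p, lags * 2))), 0.03)
})

test_that("gamma count sampling matches the target moments and dispersion", {
  set.seed(11)
  st <- data_stats(n_trials = 200, window_ms = 1000, bin_ms = 2,
                   count_mean = 2, count_variance = 2.8)
  A <- simulate_ou_mixture(ou_params(c(5, 80), c(0.5, 0.5), 1), 200, 500, 2)
  cnt <- sample_counts(A, st, alpha = 1)
  expect_equal(mean(cnt), 2, tolerance = 0.02)      # 1e5 bins, within 2%
  expect_equal(var(as.vector(cnt)), 2.8, tolerance = 0.02)
  # alpha = 1 with (nearly) constant rate: variance/mean ~ 1 (Poisson-like)
  st0 <- data_stats(100, 1000, 2, 5, 5.0001)
  cnt0 <- sample_counts(matrix(0, 100, 500), st0, alpha = 1)
  expect_equal(var(as.vector(cnt0)) / mean(cnt0), 1, tolerance = 0.05)
  # zero-rate bins give zero counts
  stz <- data_stats(2, 10, 2, 0, 0)
  expect_true(all(sample_counts(matrix(-1, 2, 5), stz, 1) == 0))
  # infeasible target variance errors out with a diagnostic
  expect_error(sample_counts(A, data_stats(10, 10, 2, 2, 1), alpha = 1),
               "infeasible")
})

test_that("matched datasets honor the statistics and are seed-reproducible", {
  st <- data_stats(17, 300, 2, 0.6, 0.9)
  p <- ou_params(c(10, 60), c(0.4, 0.6), 1.1)
  set.seed(12); a <- generate_matched_dataset(p, st)
  set.seed(12); b <- generate_matched_dataset(p, st)
  expect_identical(a$counts, b$counts)
  expect_equal(nrow(a$counts), 17L)
  expect_equal(ncol(a$counts), 150L)
})

test_that("windowed estimates of synthetic data carry the finite-window bias", {
  # the windowed AC of matched data is biased below the closed-form latent
  # AC at slow timescales, and two independent synthetic cohorts share the
  # same expected bias
  set.seed(13)
  p <- ou_params(c(5, 100), c(0.3, 0.7), 1)
  st <- data_stats(300, 500, 2, 2, 2.8)
  ac1 <- observed_ac(p, st, 50)
  ac2 <- observed_ac(p, st, 50)
  lags <- ac1$lags_ms
  latent <- ou_mixture_ac(p, lags)
  rate_share <- (st$count_variance - st$count_mean) / st$count_variance
  sel <- lags >= 20 & lags <= 100
  expect_true(all(ac1$values[sel] < rate_share * latent[sel]))
  expect_lt(mean(abs(ac1$values[sel] - ac2$values[sel])), 0.015)
})

test_that("compiled ABC kernel agrees with the R generative path", {
  # dual route: same model, same statistics, independent implementations
  set.seed(14)
  p <- ou_params(c(10, 100), c(0.5, 0.5), 1.1)
  st <- data_stats(40, 500, 2, 0.6, 0.9)
  nrep <- 150
  accR <- replicate(nrep, observed_ac(p, st, 25)$values)
  accC <- replicate(nrep, multitau:::cpp_matched_ac(p$tau, p$c_k, p$alpha,
                                                    40L, 250L, 2, 0.6, 0.9,
                                                    25L))
  z <- (rowMeans(accR) - rowMeans(accC)) /
    sqrt(apply(accR, 1, var) / nrep + apply(accC, 1, var) / nrep)
  expect_lt(max(abs(z[-1])), 4)                     # no systematic deviation
  expect_equal(accR[1, 1], accC[1, 1], tolerance = 1e-6)  # lag-0 identity
})

test_that("law of total variance shows up as the lag-0 to lag-1 drop", {
  # count variance = alpha * mean + rate variance; the AC drop between lag 0
  # and the first lag reflects the point-process share of the variance
  # the finite-window bias is identical for matched datasets, so comparing
  # two dispersions at the same total moments isolates the share term:
  # AC_a(1) - AC_b(1) = (alpha_b - alpha_a) * mean / var * exp(-bin/tau)
  set.seed(15)
  st <- data_stats(200, 2000, 2, 2, 4)
  p_lo <- ou_params(30, 1, 0.8); p_hi <- ou_params(30, 1, 1.6)
  ac_lo <- observed_ac(p_lo, st, 3)
  ac_hi <- observed_ac(p_hi, st, 3)
  share_gap <- (1.6 - 0.8) * st$count_mean / st$count_variance
  # both values share the same multiplicative finite-window attenuation, so
  # the ratio isolates the variance shares exactly
  share_lo <- (4 - 0.8 * 2) / 4; share_hi <- (4 - 1.6 * 2) / 4
  expect_equal(ac_lo$values[2] / ac_hi$values[2], share_lo / share_hi,
               tolerance = 0.1)
  expect_equal(ac_lo$values[2] - ac_hi$values[2],
               share_gap * exp(-2 / 30), tolerance = 0.2)
  expect_gt(ac_lo$values[2], ac_hi$values[2])
})
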