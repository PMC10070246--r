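test_that("binning pools channels, chops windows and drops short trials", {
  tt <- toy_events()
  bc <- bin_and_pool(tt$events, tt$trials, bin_ms = 2, window_ms = 6)
  expect_equal(nrow(bc$counts), 2L)
  expect_equal(bc$counts[1, ], c(1, 2, 0))          # spikes at 1, 3, 3 ms
  expect_equal(bc$counts[2, ], c(1, 0, 1))

  # 1900 ms trial with 700 ms windows: 2 windows kept, remainder discarded
  ev <- data.frame(trial = 1L, channel = 1L, time_ms = c(10, 1800),
                   condition = "a")
  tr <- data.frame(trial = 1L, duration_ms = 1900, condition = "a")
  bc2 <- bin_and_pool(ev, tr, bin_ms = 2, window_ms = 700)
  expect_equal(nrow(bc2$counts), 2L)
  expect_equal(sum(bc2$counts), 1L)                 # 1800 ms falls in remainder

  # trial shorter than the window is dropped and logged
  tr3 <- data.frame(trial = 1:2, duration_ms = c(500, 900), condition = "a")
  ev3 <- data.frame(trial = c(1L, 2L), channel = 1L, time_ms = c(100, 100),
                    condition = "a")
  bc3 <- bin_and_pool(ev3, tr3, bin_ms = 2, window_ms = 700)
  expect_equal(nrow(bc3$counts), 1L)
  expect_equal(bc3$dropped$trial, 1L)
  expect_match(bc3$dropped$reason, "shorter")

  expect_error(bin_and_pool(tt$events, tt$trials, bin_ms = 2, window_ms = 7),
               "multiple")
  expect_error(bin_and_pool(tt$events[0, ], tt$trials, 2, 6,
                            channels = integer(0)), "empty")
})

test_that("condition-mean subtraction centers each condition independently", {
  bc <- structure(list(counts = rbind(c(1, 2), c(3, 4), c(10, 10), c(20, 30)),
                       bin_ms = 2, window_ms = 4,
                       condition = c("a", "a", "b", "b"), trial = 1:4,
                       dropped = data.frame()), class = "binned_counts")
  out <- subtract_condition_mean(bc)
  expect_equal(out$counts[1:2, ], rbind(c(-1, -1), c(1, 1)))
  for (cd in c("a", "b"))
    expect_equal(colMeans(out$counts[bc$condition == cd, ]), c(0, 0))

  # identical windows give all-zero residuals
  bc$counts <- rbind(c(1, 2), c(1, 2), c(5, 5), c(5, 5))
  expect_true(all(subtract_condition_mean(bc)$counts == 0))

  bc$condition <- c("a", "a", "a", "b")              # single-window condition
  expect_error(subtract_condition_mean(bc), "single window")
})

test_that("windowed autocorrelation is exactly (N-1)/N at lag zero", {
  set.seed(1)
  for (N in c(5, 20, 250)) {
    x <- rnorm(N)
    cf <- autocorrelation(x, bin_ms = 2, max_lag_bins = 3)
    expect_equal(cf$values[1], (N - 1) / N, tolerance = 1e-12)
  }
  expect_error(autocorrelation(rep(1, 10)), "zero variance")
  expect_error(autocorrelation(c(1, 2)), "at least 3")
})

test_that("windowed autocorrelation matches a direct transcription of the estimator", {
  # independent brute-force evaluation with explicit lag-dependent means
  set.seed(2)
  x <- rnorm(40)
  N <- 40
  sigma2 <- (sum(x^2) - sum(x)^2 / N) / (N - 1)
  brute <- sapply(0:10, function(j) {
    i <- 1:(N - j)
    mu1 <- mean(x[i]); mu2 <- mean(x[i + j])
    sum((x[i] - mu1) * (x[i + j] - mu2)) / (sigma2 * (N - j))
  })
  cf <- autocorrelation(x, max_lag_bins = 10)
  expect_equal(cf$values, brute, tolerance = 1e-12)
})

test_that("white-noise windowed autocorrelation matches its exact small-sample bias", {
  # for iid input the estimator's expectation at lag j >= 1 is
  # -(N - 2j) / (N - j)^2 (from the covariance of the two lag-dependent
  # means); with 1e4 windows the empirical mean must sit within 3-4 s.e.
  set.seed(3)
  N <- 30
  X <- matrix(rnorm(1e4 * N), nrow = 1e4)
  acm <- multitau:::windowed_ac_matrix(X, 5)
  m <- colMeans(acm)[-1]
  se <- apply(acm[, -1], 2, sd) / sqrt(nrow(X))
  j <- 1:5
  pred <- -(N - 2 * j) / (N - j)^2
  expect_true(all(abs(m - pred) < 3.5 * se))
  expect_true(all(abs(m) < 0.05))                  # and it is small outright
})

test_that("averaging correlation functions is linear and checks grids", {
  cf1 <- corr_function(c(0, 2), c(1, 0), "auto")
  cf2 <- corr_function(c(0, 2), c(0, 1), "auto")
  avg <- average_correlations(list(cf1, cf2))
  expect_equal(avg$values, c(0.5, 0.5))
  expect_equal(avg$n_windows, 2L)
  same <- average_correlations(list(cf1, cf1, cf1))
  expect_equal(same$values, cf1$values)             # idempotent on copies
  bad <- corr_function(c(0, 4), c(0, 1), "auto")
  expect_error(average_correlations(list(cf1, bad)), "grids")
})

test_that("cross-correlation matches the autocorrelation algebra and spacing rule", {
  set.seed(4)
  x <- rnorm(50)
  cc <- cross_correlation(x, x, max_lag_bins = 4)
  expect_equal(cc$values[1], 49 / 50, tolerance = 1e-12)  # self at lag 0
  a <- rnorm(200); b <- rnorm(200)
  cci <- cross_correlation(a, b, max_lag_bins = 0)
  expect_lt(abs(cci$values[1]), 3 / sqrt(200))
  expect_error(cross_correlation(a, b, channel_a = 1, channel_b = 2),
               "rejected")
  expect_silent(cross_correlation(a, b, max_lag_bins = 2,
                                  channel_a = 1, channel_b = 3))
  # asymmetric in (a, b) at nonzero lag: a leads
  ab <- cross_correlation(a, b, max_lag_bins = 3)
  ba <- cross_correlation(b, a, max_lag_bins = 3)
  expect_false(isTRUE(all.equal(ab$values[-1], ba$values[-1])))
})

test_that("session QC excludes autocorrelations that dip early", {
  lags <- seq(0, 100, by = 2)
  good <- corr_function(lags, 0.5 * exp(-lags / 50), "auto")
  expect_true(session_qc(good))                      # AC(20) = 0.335
  vals <- 0.5 * exp(-lags / 50); vals[lags == 16] <- 0.005
  expect_false(session_qc(corr_function(lags, vals, "auto")))
  noisy <- 0.5 * exp(-lags / 3)                      # below 0.01 by lag 12
  expect_false(session_qc(corr_function(lags, noisy, "auto")))
})

test_that("RF-distance split groups pairs at the median into the short group", {
  rf <- data.frame(channel = 1:5, x_dva = c(0, 1, 2, 3, 4), y_dva = 0)
  pairs <- data.frame(a = c(1, 1, 1, 1), b = c(2, 3, 4, 5))  # d = 1,2,3,4
  ccs <- lapply(1:4, function(i)
    corr_function(c(0, 2), c(i, i / 2), "cross"))
  g <- group_cc_by_rf_distance(ccs, pairs, rf)
  expect_equal(g$median_distance, 2.5)
  expect_equal(g$short$values, c(1.5, 0.75))         # mean of pairs 1, 2
  expect_equal(g$long$values, c(3.5, 1.75))
  # a pair exactly at the median joins the short group
  pairs2 <- data.frame(a = c(1, 1, 1), b = c(2, 3, 5))  # d = 1, 2, 4; med 2
  g2 <- group_cc_by_rf_distance(ccs[1:3], pairs2, rf)
  expect_equal(g2$short$n_windows, 2L)
  expect_error(group_cc_by_rf_distance(ccs[1:2],
                                       data.frame(a = c(1, 2), b = c(2, 3)),
                                       rf), "single")
})
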