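#' Correlation function container
#'
#' A lagged correlation estimate together with its provenance: the lag grid
#' (ms), the estimator kind ("auto" or "cross"), the number of windows that
#' were averaged, and the bin size.
#'
#' @param lags_ms numeric vector of non-negative lags in ms.
#' @param values numeric vector of correlation values, one per lag.
#' @param kind "auto" or "cross".
#' @param n_windows number of windows averaged into `values`.
#' @param bin_ms bin size in ms.
#' @param condition optional condition label.
#' @return An object of class `corr_function`.
#' @export
corr_function <- function(lags_ms, values, kind = c("auto", "cross"),
                          n_windows = 1L, bin_ms = 2, condition = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(length(lags_ms) == length(values), all(lags_ms >= 0),
            all(is.finite(values)))
  structure(list(lags_ms = as.numeric(lags_ms), values = as.numeric(values),
                 kind = kind, n_windows = as.integer(n_windows),
                 bin_ms = bin_ms, condition = condition,
                 zero_lag_included = lags_ms[1] == 0),
            class = "corr_function")
}

#' @export
print.corr_function <- function(x, ...) {
  cat(sprintf("<corr_function> %scorrelation, %d lags (%.0f..%.0f ms), %d window(s)\n",
              if (x$kind == "auto") "auto" else "cross-",
              length(x$lags_ms), min(x$lags_ms), max(x$lags_ms), x$n_windows))
  invisible(x)
}

#' @export
as.data.frame.corr_function <- function(x, ...) {
  data.frame(lag_ms = x$lags_ms, value = x$values, kind = x$kind,
             condition = x$condition, n_windows = x$n_windows)
}

#' Bin pooled spike counts into fixed-length windows
#'
#' Pools spikes from the selected channels of every trial, counts them in
#' `bin_ms` bins over the trial's analysis epoch, and chops each trial into
#' as many non-overlapping windows of `window_ms` as fit; the remainder is
#' discarded. Trials shorter than one window are dropped (and logged).
#'
#' @param events data.frame with columns `trial`, `channel`, `time_ms`,
#'   `condition` (spike times in ms from epoch start).
#' @param trials data.frame with columns `trial`, `duration_ms`, `condition`
#'   giving the epoch duration of every trial (trials without spikes still
#'   contribute empty windows).
#' @param bin_ms bin size in ms (default 2).
#' @param window_ms window length in ms; must be a multiple of `bin_ms`.
#' @param channels channel selection (default: all channels present).
#' @return A `binned_counts` object: `counts` (window x bin matrix),
#'   per-window `condition` and `trial` labels, and a `dropped` log.
#' @export
bin_and_pool <- function(events, trials, bin_ms = 2, window_ms,
                         channels = NULL) {
  if (window_ms %% bin_ms != 0)
    stop("window_ms must be a multiple of bin_ms")
  if (is.null(channels)) channels <- sort(unique(events$channel))
  if (length(channels) == 0) stop("empty channel selection")
  events <- events[events$channel %in% channels, , drop = FALSE]
  nb <- as.integer(window_ms / bin_ms)

  counts <- list(); cond <- character(0); trial_of <- c(); dropped <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials$trial[i]; dur <- trials$duration_ms[i]
    nw <- floor(dur / window_ms)
    if (nw < 1) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trial = tr, reason = "shorter than window")
      next
    }
    st <- events$time_ms[events$trial == tr]
    if (any(st < 0 | st >= dur)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trial = tr, reason = "spike outside epoch")
      next
    }
    total_ms <- nw * window_ms
    st <- st[st < total_ms]
    h <- tabulate(pmin(floor(st / bin_ms) + 1L, nw * nb), nbins = nw * nb)
    m <- matrix(h, nrow = nw, ncol = nb, byrow = TRUE)
    counts[[length(counts) + 1L]] <- m
    cond <- c(cond, rep(as.character(trials$condition[i]), nw))
    trial_of <- c(trial_of, rep(tr, nw))
  }
  if (length(counts) == 0) stop("no trial long enough for one window")
  structure(list(counts = do.call(rbind, counts), bin_ms = bin_ms,
                 window_ms = window_ms, condition = cond, trial = trial_of,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(trial = integer(0),
                                           reason = character(0))),
            class = "binned_counts")
}

#' Subtract the per-condition mean count at each bin
#'
#' Removes correlations locked to task events by subtracting, within each
#' behavioral condition, the across-window mean count at every bin position.
#' After subtraction each condition's per-bin column mean is zero.
#'
#' @param bc a `binned_counts` object.
#' @return The same object with real-valued, mean-subtracted `counts`.
#' @export
subtract_condition_mean <- function(bc) {
  stopifnot(inherits(bc, "binned_counts"))
  out <- bc$counts * 1.0
  for (cd in unique(bc$condition)) {
    idx <- which(bc$condition == cd)
    if (length(idx) < 2)
      stop("condition '", cd, "' has a single window; mean subtraction ",
           "would zero the data")
    mu <- colMeans(bc$counts[idx, , drop = FALSE])
    out[idx, ] <- sweep(bc$counts[idx, , drop = FALSE], 2, mu)
  }
  bc$counts <- out
  bc
}

# Windowed autocorrelation, vectorized across the rows of X.
# Per window of length N and lag j it uses the two lag-dependent sample means
# mu1(j), mu2(j) and a single (N-1)-normalized sample variance:
#   AC(j) = sum_{i<=N-j} (A_i - mu1)(A_{i+j} - mu2) / (sigma^2 (N - j)).
# At j = 0 this equals (N-1)/N for every non-constant window.
windowed_ac_matrix <- function(X, max_lag_bins) {
  N <- ncol(X); W <- nrow(X)
  stopifnot(max_lag_bins < N)
  s1 <- rowSums(X); s2 <- rowSums(X^2)
  sigma2 <- (s2 - s1^2 / N) / (N - 1)
  ok <- sigma2 > 0
  ac <- matrix(NA_real_, W, max_lag_bins + 1L)
  for (j in 0:max_lag_bins) {
    n <- N - j
    A1 <- X[, 1:n, drop = FALSE]
    A2 <- X[, (j + 1):N, drop = FALSE]
    mu1 <- rowSums(A1) / n; mu2 <- rowSums(A2) / n
    ac[, j + 1L] <- (rowSums(A1 * A2) - n * mu1 * mu2) / (sigma2 * n)
  }
  ac[!ok, ] <- NA_real_
  ac
}

#' Single-window autocorrelation with lag-dependent means
#'
#' The windowed spike-count autocorrelation estimator: at each lag the two
#' overlapping segments are centered by their own sample means, and the
#' product sum is normalized by a single sample variance with an (N-1)
#' denominator. The zero-lag value is exactly (N-1)/N.
#'
#' @param x numeric window (length >= 3, non-constant).
#' @param bin_ms bin size in ms.
#' @param max_lag_bins maximum lag in bins (default N-1).
#' @return A `corr_function`.
#' @export
autocorrelation <- function(x, bin_ms = 2, max_lag_bins = length(x) - 1L) {
  if (length(x) < 3) stop("window must have at least 3 bins")
  if (stats::var(x) <= 0) stop("window has zero variance; autocorrelation undefined")
  ac <- windowed_ac_matrix(matrix(x, nrow = 1), max_lag_bins)[1, ]
  corr_function((0:max_lag_bins) * bin_ms, ac, "auto", 1L, bin_ms)
}

#' Average correlation functions over windows
#'
#' Unweighted mean across a list of `corr_function`s on identical lag grids;
#' `n_windows` accumulates.
#'
#' @param cfs list of `corr_function` objects.
#' @return A `corr_function`.
#' @export
average_correlations <- function(cfs) {
  stopifnot(length(cfs) >= 1, all(vapply(cfs, inherits, TRUE, "corr_function")))
  grid <- cfs[[1]]$lags_ms
  for (cf in cfs) if (!isTRUE(all.equal(cf$lags_ms, grid)))
    stop("mixed lag grids; cannot average")
  vals <- rowMeans(vapply(cfs, `[[`, numeric(length(grid)), "values"))
  corr_function(grid, vals, cfs[[1]]$kind,
                sum(vapply(cfs, `[[`, integer(1), "n_windows")),
                cfs[[1]]$bin_ms, cfs[[1]]$condition)
}

#' Condition-averaged windowed autocorrelation of binned counts
#'
#' Convenience wrapper: computes the windowed autocorrelation of every window
#' in `bc` and averages within each behavioral condition. Windows with zero
#' variance are excluded (counted in the result's attributes).
#'
#' @param bc a `binned_counts` object (typically mean-subtracted).
#' @param max_lag_ms maximum lag in ms.
#' @param conditions conditions to keep (default all).
#' @return Named list of `corr_function`s, one per condition.
#' @export
condition_autocorrelations <- function(bc, max_lag_ms = 100,
                                       conditions = unique(bc$condition)) {
  ml <- as.integer(max_lag_ms / bc$bin_ms)
  acm <- windowed_ac_matrix(bc$counts, ml)
  out <- list()
  for (cd in conditions) {
    rows <- which(bc$condition == cd)
    sub <- acm[rows, , drop = FALSE]
    keep <- stats::complete.cases(sub)
    vals <- colMeans(sub[keep, , drop = FALSE])
    cf <- corr_function((0:ml) * bc$bin_ms, vals, "auto", sum(keep),
                        bc$bin_ms, cd)
    attr(cf, "n_excluded") <- sum(!keep)
    out[[as.character(cd)]] <- cf
  }
  out
}

#' Windowed cross-correlation between two channels
#'
#' Cross-correlation between mean-subtracted count series of two channels,
#' with per-channel lag-dependent sample means and normalization by the
#' geometric mean of the two sample variances. Asymmetric in (a, b) at
#' nonzero lag: `a` leads. When channel indices are supplied, adjacent pairs
#' (|a - b| < 2) are rejected, matching the spacing rule used to avoid shared
#' spike contamination on neighboring channels.
#'
#' @param a,b numeric windows of equal length.
#' @param bin_ms bin size in ms.
#' @param max_lag_bins maximum lag in bins.
#' @param channel_a,channel_b optional integer channel indices.
#' @return A `corr_function` of kind "cross".
#' @export
cross_correlation <- function(a, b, bin_ms = 2,
                              max_lag_bins = length(a) - 1L,
                              channel_a = NULL, channel_b = NULL) {
  if (length(a) != length(b)) stop("windows must have equal length")
  if (!is.null(channel_a) && !is.null(channel_b) &&
      abs(channel_a - channel_b) < 2)
    stop("channel pair rejected: |a - b| must be >= 2")
  N <- length(a)
  va <- stats::var(a); vb <- stats::var(b)
  if (va <= 0 || vb <= 0) stop("zero variance in one of the windows")
  cc <- numeric(max_lag_bins + 1L)
  for (j in 0:max_lag_bins) {
    n <- N - j
    A <- a[1:n]; B <- b[(j + 1):N]
    cc[j + 1L] <- sum((A - mean(A)) * (B - mean(B))) / (sqrt(va * vb) * n)
  }
  corr_function((0:max_lag_bins) * bin_ms, cc, "cross", 1L, bin_ms)
}

#' Session quality control on an averaged autocorrelation
#'
#' A session is excluded when its autocorrelation falls below `threshold`
#' (default 0.01) at any lag up to `max_lag_ms` (default 20 ms): such
#' correlations are dominated by noise or oscillations and cannot be
#' described by a mixture of exponential decays.
#'
#' @param cf a `corr_function`.
#' @param threshold exclusion threshold (default 0.01).
#' @param max_lag_ms lags checked (default 20 ms).
#' @return TRUE to include, FALSE to exclude.
#' @export
session_qc <- function(cf, threshold = 0.01, max_lag_ms = 20) {
  stopifnot(inherits(cf, "corr_function"))
  sel <- cf$lags_ms <= max_lag_ms
  !any(cf$values[sel] < threshold)
}

#' Split cross-correlations by receptive-field-center distance
#'
#' Computes the Euclidean distance between the RF centers of every channel
#' pair, splits the pairs at the median distance (pairs exactly at the
#' median go to the short-distance group), and averages the
#' cross-correlations within each group.
#'
#' @param ccs list of `corr_function`s, one per channel pair.
#' @param pairs data.frame with columns `a`, `b` (channel indices), aligned
#'   with `ccs`.
#' @param rf data.frame with columns `channel`, `x_dva`, `y_dva`.
#' @return List with `short`, `long` (`corr_function`s), `median_distance`,
#'   and the per-pair `distances`.
#' @export
group_cc_by_rf_distance <- function(ccs, pairs, rf) {
  stopifnot(length(ccs) == nrow(pairs))
  idx <- match(pairs$a, rf$channel); jdx <- match(pairs$b, rf$channel)
  if (anyNA(idx) || anyNA(jdx)) stop("channel missing from RF map")
  d <- sqrt((rf$x_dva[idx] - rf$x_dva[jdx])^2 +
            (rf$y_dva[idx] - rf$y_dva[jdx])^2)
  if (length(unique(d)) < 2) stop("all pairs at a single RF distance")
  med <- stats::median(d)
  short <- d <= med
  list(short = average_correlations(ccs[short]),
       long = average_correlations(ccs[!short]),
       median_distance = med, distances = d)
}
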