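#' Configuration for adaptive ABC fitting
#'
#' Defaults follow the reference procedure: uniform priors (fast timescale
#' up to 60 ms, slow up to 400 ms, weight in `[0,1]`, dispersion in
#' `[0.7, 1.3]`), initial error threshold 0.1, 100 accepted samples per
#' iteration, stop when the acceptance rate falls below 7e-4, distances
#' computed up to 100 ms. `excluded_lags_ms` removes individual lags from the
#' distance (e.g. the first lag when refractoriness distorts it); whether the
#' zero lag is fitted is controlled by `fit_zero_lag`.
#'
#' @param eps0 initial error threshold.
#' @param samples_per_iter accepted samples per iteration (posterior size).
#' @param accR_stop stop when the iteration acceptance rate drops below this.
#' @param t_m_ms maximum lag entering the distance (ms).
#' @param excluded_lags_ms lags (ms) excluded from the distance.
#' @param fit_zero_lag include the zero lag in the distance (default TRUE;
#'   the lag-0 drop carries the dispersion information).
#' @param max_iter hard cap on iterations.
#' @param draw_cap per-iteration cap on candidate draws (abort guard).
#' @param priors optional named list overriding per-model prior boxes; each
#'   entry a 2 x d matrix (rows lo, hi).
#' @param map_grid_n grid points per dimension for the MAP search (default
#'   50 for <= 2 parameters, 20 otherwise).
#' @return An `abc_config` object.
#' @export
abc_config <- function(eps0 = 0.1, samples_per_iter = 100L,
                       accR_stop = 7e-4, t_m_ms = 100,
                       excluded_lags_ms = numeric(0), fit_zero_lag = TRUE,
                       max_iter = 30L, draw_cap = 1e6, priors = NULL,
                       map_grid_n = NULL) {
  stopifnot(eps0 > 0, samples_per_iter >= 2, accR_stop > 0, t_m_ms > 0)
  structure(list(eps0 = eps0, samples_per_iter = as.integer(samples_per_iter),
                 accR_stop = accR_stop, t_m_ms = t_m_ms,
                 excluded_lags_ms = excluded_lags_ms,
                 fit_zero_lag = fit_zero_lag, max_iter = as.integer(max_iter),
                 draw_cap = draw_cap, priors = priors,
                 map_grid_n = map_grid_n), class = "abc_config")
}

# Default uniform prior boxes per generative model.
abc_prior_box <- function(model, cfg = NULL) {
  if (!is.null(cfg$priors) && !is.null(cfg$priors[[model]]))
    return(cfg$priors[[model]])
  switch(model,
    M1 = rbind(lo = c(tau = 0, alpha = 0.7),
               hi = c(tau = 400, alpha = 1.3)),
    M2 = rbind(lo = c(tau1 = 0, tau2 = 0, c1 = 0, alpha = 0.7),
               hi = c(tau1 = 60, tau2 = 400, c1 = 1, alpha = 1.3)),
    M3 = rbind(lo = c(tau1 = 0, tau2 = 0, tau3 = 0, c1 = 0, c2 = 0,
                      alpha = 0.7),
               hi = c(tau1 = 60, tau2 = 400, tau3 = 400, c1 = 1, c2 = 1,
                      alpha = 1.3)),
    stop("unknown model: ", model))
}

# Turn a raw parameter vector into ou_params (sorting timescales for
# identifiability). Returns NULL for invalid weight combinations (M3).
abc_theta_to_params <- function(theta, model) {
  if (model == "M1") {
    if (theta[1] <= 0) return(NULL)
    ou_params(theta[1], 1, theta[2])
  } else if (model == "M2") {
    if (any(theta[1:2] <= 0)) return(NULL)
    ou_params(theta[1:2], c(theta[3], 1 - theta[3]), theta[4])
  } else {
    if (any(theta[1:3] <= 0) || theta[4] + theta[5] > 1) return(NULL)
    ou_params(theta[1:3], c(theta[4], theta[5], 1 - theta[4] - theta[5]),
              theta[6])
  }
}

# Sort the timescale block of a sampled vector (label-switching control).
abc_sort_taus <- function(theta, model) {
  nt <- switch(model, M1 = 1L, M2 = 2L, M3 = 3L)
  if (nt > 1) theta[1:nt] <- sort(theta[1:nt])
  theta
}

#' Distance between two correlation functions
#'
#' Mean squared difference over the lags from 0 to `t_m_ms`, normalized by
#' m = t_m / bin (so 51 lags are summed and divided by 50 for t_m = 100 ms
#' at 2 ms bins). Lags listed in `excluded_lags_ms` (and lag 0 when
#' `fit_zero_lag` is FALSE) are dropped from the sum; the normalization is
#' kept at 1/m.
#'
#' @param ac_data,ac_synth `corr_function`s on a common lag grid, or plain
#'   numeric vectors assumed to start at lag 0 on the same grid.
#' @param t_m_ms maximum lag (ms).
#' @param bin_ms bin size (needed when passing bare vectors).
#' @param excluded_lags_ms lags dropped from the sum.
#' @param fit_zero_lag include lag 0.
#' @return Non-negative scalar distance.
#' @export
ac_distance <- function(ac_data, ac_synth, t_m_ms = 100, bin_ms = NULL,
                        excluded_lags_ms = numeric(0), fit_zero_lag = TRUE) {
  if (inherits(ac_data, "corr_function")) {
    bin_ms <- ac_data$bin_ms
    lags <- ac_data$lags_ms; x <- ac_data$values
  } else {
    if (is.null(bin_ms)) stop("bin_ms required for bare vectors")
    lags <- (seq_along(ac_data) - 1) * bin_ms; x <- ac_data
  }
  if (inherits(ac_synth, "corr_function")) {
    if (!isTRUE(all.equal(ac_synth$lags_ms[seq_len(min(length(ac_synth$lags_ms),
                                                       length(lags)))],
                          lags[seq_len(min(length(ac_synth$lags_ms),
                                           length(lags)))])))
      stop("lag grids do not match")
    y <- ac_synth$values
  } else y <- ac_synth
  m <- t_m_ms / bin_ms
  keep <- lags <= t_m_ms & !(lags %in% excluded_lags_ms)
  if (!fit_zero_lag) keep <- keep & lags > 0
  n <- min(length(x), length(y), sum(lags <= t_m_ms))
  keep <- keep[seq_len(n)]
  sum((x[seq_len(n)][keep] - y[seq_len(n)][keep])^2) / m
}

# Windowed, window-averaged AC of a matched synthetic dataset for a raw
# parameter vector; the exact pipeline applied to the data. Runs through the
# compiled kernel (cpp_matched_ac), which mirrors the R reference path
# (simulate_ou_mixture + sample_counts + windowed_ac_matrix).
abc_synth_ac <- function(theta, model, stats_, max_lag_bins) {
  params <- abc_theta_to_params(theta, model)
  if (is.null(params)) return(NULL)
  nb <- as.integer(stats_$window_ms / stats_$bin_ms)
  ac <- cpp_matched_ac(params$tau, params$c_k, params$alpha,
                       stats_$n_trials, nb, stats_$bin_ms,
                       stats_$count_mean, stats_$count_variance,
                       max_lag_bins)
  if (anyNA(ac)) return(NULL)
  ac
}

# Gaussian kernel density of points `at` given particles/weights/cov factor.
abc_kernel_density <- function(at, particles, weights, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) { # degenerate covariance: fall back to diagonal + jitter
    d <- diag(sigma); d[d <= 0] <- max(d, 1e-12) * 1e-6 + 1e-12
    ch <- chol(diag(d, nrow = length(d)))
  }
  logdet <- sum(log(diag(ch)))
  d <- ncol(particles)
  apply(at, 1, function(th) {
    z <- backsolve(ch, t(particles) - th, transpose = TRUE)
    sum(weights * exp(-0.5 * colSums(z^2) - logdet -
                        0.5 * d * log(2 * pi)))
  })
}

#' Fit the OU-mixture generative model with adaptive ABC
#'
#' Population Monte Carlo ABC: the first iteration draws from the uniform
#' prior; subsequent iterations resample previously accepted particles
#' (proportionally to their importance weights), perturb them with a
#' Gaussian kernel whose covariance is twice the weighted sample covariance,
#' truncate to the prior support, and reweight. Every candidate is mapped to
#' a matched synthetic dataset whose windowed autocorrelation is compared to
#' the data's with [ac_distance()]; candidates below the current threshold
#' are accepted. After each iteration the threshold shrinks to the first
#' quartile of the accepted distances; the loop stops when the acceptance
#' rate falls below `cfg$accR_stop` (or `max_iter` / the draw cap is hit).
#'
#' @param ac_data `corr_function` of the observed (condition-averaged)
#'   autocorrelation.
#' @param stats_ `data_stats` of the observed counts.
#' @param model "M1" (one timescale), "M2" (two) or "M3" (three).
#' @param cfg an [abc_config()].
#' @param verbose print per-iteration progress.
#' @return A `posterior_ensemble`: accepted `samples` (matrix), importance
#'   `weights`, accepted `distances`, `eps_history`, `accR_history`, the
#'   model tag, prior box and stop reason.
#' @export
abc_fit <- function(ac_data, stats_, model = c("M2", "M1", "M3"),
                    cfg = abc_config(), verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(ac_data, "corr_function"), inherits(stats_, "data_stats"))
  box <- abc_prior_box(model, cfg)
  d <- ncol(box)
  npart <- cfg$samples_per_iter
  max_lag_bins <- as.integer(cfg$t_m_ms / stats_$bin_ms)
  if (max_lag_bins + 1L > length(ac_data$values))
    stop("observed AC does not reach t_m")

  dist_fun <- function(synth_ac)
    ac_distance(ac_data$values[seq_len(max_lag_bins + 1L)], synth_ac,
                t_m_ms = cfg$t_m_ms, bin_ms = stats_$bin_ms,
                excluded_lags_ms = cfg$excluded_lags_ms,
                fit_zero_lag = cfg$fit_zero_lag)

  eps <- cfg$eps0
  eps_history <- accR_history <- numeric(0)
  particles <- NULL; weights <- NULL; dists <- NULL
  stop_reason <- "max_iter"

  for (iter in seq_len(cfg$max_iter)) {
    acc <- matrix(NA_real_, npart, d, dimnames = list(NULL, colnames(box)))
    acc_d <- numeric(npart)
    n_acc <- 0L; n_draw <- 0L
    if (iter > 1) {
      sigma <- 2 * stats::cov.wt(particles, wt = weights)$cov
      ch <- tryCatch(chol(sigma), error = function(e) NULL)
    }
    while (n_acc < npart) {
      if (n_draw >= cfg$draw_cap) {
        stop("acceptance collapsed: ", n_draw, " draws, ", n_acc,
             " accepted at eps = ", signif(eps, 3))
      }
      if (iter == 1) {
        theta <- box["lo", ] + stats::runif(d) * (box["hi", ] - box["lo", ])
      } else {
        repeat {
          i <- sample.int(npart, 1, prob = weights)
          if (!is.null(ch)) {
            theta <- particles[i, ] + drop(stats::rnorm(d) %*% ch)
          } else {
            theta <- particles[i, ] + stats::rnorm(d, 0,
                       sqrt(pmax(diag(sigma), 1e-12)))
          }
          if (all(theta >= box["lo", ] & theta <= box["hi", ])) break
        }
      }
      theta <- abc_sort_taus(theta, model)
      n_draw <- n_draw + 1L
      synth <- abc_synth_ac(theta, model, stats_, max_lag_bins)
      if (is.null(synth)) next
      dd <- dist_fun(synth)
      if (dd < eps) {
        n_acc <- n_acc + 1L
        acc[n_acc, ] <- theta
        acc_d[n_acc] <- dd
      }
    }
    accR <- n_acc / n_draw
    if (iter == 1) {
      new_w <- rep(1 / npart, npart)
    } else {
      dens <- abc_kernel_density(acc, particles, weights, sigma)
      new_w <- 1 / pmax(dens, .Machine$double.xmin)
      new_w <- new_w / sum(new_w)
    }
    particles <- acc; weights <- new_w; dists <- acc_d
    eps_history <- c(eps_history, eps)
    accR_history <- c(accR_history, accR)
    if (verbose)
      message(sprintf("iter %d: eps=%.4g accR=%.4g", iter, eps, accR))
    eps <- min(eps, stats::quantile(acc_d, 0.25, names = FALSE))
    if (accR < cfg$accR_stop) { stop_reason <- "accR"; break }
  }

  structure(list(samples = particles, weights = weights, distances = dists,
                 eps_history = eps_history, accR_history = accR_history,
                 model = model, prior_box = box, cfg = cfg,
                 stop_reason = stop_reason), class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("<posterior_ensemble> %s, %d samples, %d iterations (stop: %s)\n",
              x$model, nrow(x$samples), length(x$eps_history), x$stop_reason))
  invisible(x)
}

#' Maximum a posteriori estimate from an ABC ensemble
#'
#' Smooths the joint weighted ensemble with a Gaussian product kernel
#' (Scott's rule bandwidth per dimension) and maximizes it by grid search
#' over the prior box. Deterministic given the ensemble and grid; ties are
#' broken toward the first grid point in array order (i.e. lower values of
#' the earlier parameters).
#'
#' @param post a `posterior_ensemble`.
#' @param grid_n grid points per dimension (default from the config: 50 for
#'   up to two parameters, 20 otherwise).
#' @return Named numeric vector of MAP parameters.
#' @export
map_estimate <- function(post, grid_n = NULL) {
  stopifnot(inherits(post, "posterior_ensemble"))
  X <- post$samples; w <- post$weights / sum(post$weights)
  d <- ncol(X); n <- nrow(X)
  if (is.null(grid_n)) grid_n <- post$cfg$map_grid_n
  if (is.null(grid_n)) grid_n <- if (d <= 2) 50L else 20L
  sds <- sqrt(pmax(apply(X, 2, stats::var), 0))
  if (all(sds == 0)) {
    warning("degenerate ensemble: all samples identical")
    return(X[1, ])
  }
  n_eff <- 1 / sum(w^2)
  h <- sds * n_eff^(-1 / (d + 4))
  h[h == 0] <- max(h) * 1e-3
  grids <- lapply(seq_len(d), function(j)
    seq(post$prior_box["lo", j], post$prior_box["hi", j], length.out = grid_n))
  # separable kernel: accumulate the weighted outer product per particle
  kmats <- lapply(seq_len(d), function(j)
    exp(-0.5 * outer(grids[[j]], X[, j], "-")^2 / h[j]^2))
  dens <- array(0, dim = rep(grid_n, d))
  for (i in seq_len(n)) {
    o <- kmats[[1]][, i]
    if (d > 1) for (j in 2:d) o <- outer(o, kmats[[j]][, i])
    dens <- dens + w[i] * o
  }
  idx <- arrayInd(which.max(dens), dim(dens))[1, ]
  out <- vapply(seq_len(d), function(j) grids[[j]][idx[j]], numeric(1))
  names(out) <- colnames(X)
  out
}

#' Marginal posterior summaries
#'
#' Per-parameter order statistics of the final accepted ensemble (unweighted
#' on the 100-sample posterior; standard type-7 quantiles, so samples
#' 1..100 give a first quartile of 25.75).
#'
#' @param post a `posterior_ensemble`.
#' @return data.frame with mean, median, quartiles and a central 95%
#'   credible interval per parameter.
#' @export
posterior_summary <- function(post) {
  stopifnot(inherits(post, "posterior_ensemble"))
  X <- post$samples
  data.frame(parameter = colnames(X),
             mean = colMeans(X),
             median = apply(X, 2, stats::median),
             q25 = apply(X, 2, stats::quantile, 0.25, names = FALSE),
             q75 = apply(X, 2, stats::quantile, 0.75, names = FALSE),
             ci_lo = apply(X, 2, stats::quantile, 0.025, names = FALSE),
             ci_hi = apply(X, 2, stats::quantile, 0.975, names = FALSE),
             row.names = NULL)
}
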