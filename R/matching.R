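#' Fit a double exponential to an unbiased autocorrelation
#'
#' Bounded nonlinear least squares of
#' AC(t) = c1 exp(-t/tau1) + (1 - c1) exp(-t/tau2)
#' to the lags up to `t_m_ms`, multi-started from a small grid of
#' initializations (tau1 in 2/5/10 ms, tau2 in 50/150 ms, c1 = 0.5); the
#' best converged start wins and the timescales are returned sorted. Fits
#' where the two timescales collapse (ratio < 1.5) or one component
#' vanishes (c1 outside 0.01..0.99) are flagged degenerate. Intended for
#' unbiased (long-simulation) autocorrelations; biased windowed estimates
#' should be fitted with the generative-model machinery instead.
#'
#' @param cf a `corr_function` (or numeric AC values with `lags_ms`).
#' @param t_m_ms maximum fitted lag (default 100 ms).
#' @param min_lag_ms first fitted lag (default: first nonzero lag).
#' @param lags_ms lag grid when `cf` is a bare vector.
#' @return A `double_exp_fit`: `tau1 < tau2` (ms), `c1` (weight of the fast
#'   component), `residual` (RSS), `degenerate` flag.
#' @export
fit_double_exponential <- function(cf, t_m_ms = 100, min_lag_ms = NULL,
                                   lags_ms = NULL) {
  if (inherits(cf, "corr_function")) {
    lags <- cf$lags_ms; vals <- cf$values
  } else {
    stopifnot(!is.null(lags_ms)); lags <- lags_ms; vals <- cf
  }
  if (is.null(min_lag_ms)) min_lag_ms <- min(lags[lags > 0])
  sel <- lags >= min_lag_ms & lags <= t_m_ms
  t <- lags[sel]; y <- vals[sel]
  if (length(t) < 5) stop("too few lags to fit a double exponential")
  starts <- expand.grid(tau1 = c(2, 5, 10), tau2 = c(50, 150), c1 = 0.5)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c1 * exp(-t / tau1) + (1 - c1) * exp(-t / tau2),
        start = as.list(starts[s, ]),
        lower = c(tau1 = 1e-3, tau2 = 1e-3, c1 = 0),
        upper = c(tau1 = 1e3, tau2 = 1e3, c1 = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("double-exponential fit failed from all starts")
  p <- stats::coef(best$fit)
  if (p[["tau1"]] > p[["tau2"]]) {
    p <- c(tau1 = p[["tau2"]], tau2 = p[["tau1"]], c1 = 1 - p[["c1"]])
  }
  structure(list(tau1 = p[["tau1"]], tau2 = p[["tau2"]], c1 = p[["c1"]],
                 residual = best$rss, t_m_ms = t_m_ms,
                 degenerate = p[["c1"]] < 0.01 || p[["c1"]] > 0.99 ||
                   p[["tau2"]] / p[["tau1"]] < 1.5),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf("<double_exp_fit> tau1=%.3g ms, tau2=%.3g ms, c1=%.3g (RSS %.3g)%s\n",
              x$tau1, x$tau2, x$c1, x$residual,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit a single exponential decay with free amplitude
#'
#' Least-squares fit of a exp(-t/tau) over the lags in
#' `[min_lag_ms, t_m_ms]`. Used for correlation tails whose amplitude is
#' not 1 at lag 0 (e.g. the recurrent-input autocorrelation of shadow
#' units, or the pooled-activity autocorrelation).
#'
#' @inheritParams fit_double_exponential
#' @param tau_start initial timescale guess (ms).
#' @return List with `tau` (ms), `a` (amplitude) and `residual`.
#' @export
fit_exponential <- function(cf, t_m_ms = 100, min_lag_ms = NULL,
                            lags_ms = NULL, tau_start = 30) {
  if (inherits(cf, "corr_function")) {
    lags <- cf$lags_ms; vals <- cf$values
  } else {
    stopifnot(!is.null(lags_ms)); lags <- lags_ms; vals <- cf
  }
  if (is.null(min_lag_ms)) min_lag_ms <- min(lags[lags > 0])
  sel <- lags >= min_lag_ms & lags <= t_m_ms
  t <- lags[sel]; y <- vals[sel]
  fit <- minpack.lm::nlsLM(y ~ a * exp(-t / tau),
                           start = list(a = max(y), tau = tau_start),
                           lower = c(a = 0, tau = 1e-3),
                           upper = c(a = Inf, tau = 1e4),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  list(tau = p[["tau"]], a = p[["a"]],
       residual = sum(stats::residuals(fit)^2))
}

#' Target timescale ranges for network matching
#'
#' Acceptance bands (mean +/- s.e.m.) for the fast and slow timescale that
#' a matched network operating point must reproduce.
#'
#' @param tau1_mean,tau1_sem fast-timescale band (ms).
#' @param tau2_mean,tau2_sem slow-timescale band (ms).
#' @return A `match_targets` object with `tau1` and `tau2` ranges.
#' @export
match_targets <- function(tau1_mean, tau1_sem, tau2_mean, tau2_sem) {
  stopifnot(tau1_mean > 0, tau2_mean > 0, tau1_sem >= 0, tau2_sem >= 0)
  structure(list(tau1 = c(tau1_mean - tau1_sem, tau1_mean + tau1_sem),
                 tau2 = c(tau2_mean - tau2_sem, tau2_mean + tau2_sem),
                 tau1_mean = tau1_mean, tau2_mean = tau2_mean),
            class = "match_targets")
}

#' Grid search for network parameters reproducing target timescales
#'
#' For every (p_s, BP) grid point, simulates the locally connected (r = 1)
#' spatial network, fits a double exponential to the unit-averaged
#' long-run autocorrelation, and accepts the point when both fitted
#' timescales fall inside the target bands. The grid should be
#' pre-shortlisted with the analytic self-excitation and interaction
#' timescales (see [tau_self()], [tau_int_effective()]); simulation is the
#' arbiter because the analytic interaction timescale is approximate.
#'
#' @param targets a [match_targets()] object.
#' @param p_s_grid,bp_grid candidate self-excitation probabilities and
#'   branching parameters.
#' @param L lattice side for the search simulations.
#' @param steps simulation steps per grid point.
#' @param p_ext external excitation.
#' @param n_record units entering the unit-averaged autocorrelation.
#' @param t_m_ms maximum fitted lag.
#' @param n_rep independent simulations per grid point; their unit-averaged
#'   autocorrelations are averaged before fitting (near criticality single
#'   runs are dominated by the slow global mode, so replicates sharpen the
#'   timescale estimates far more than longer single runs).
#' @return A `match_grid` data.frame (p_s, p_r, bp, tau1, tau2, c1,
#'   degenerate, accepted), with the nearest miss flagged when nothing is
#'   accepted.
#' @export
grid_search_match <- function(targets, p_s_grid, bp_grid, L = 50,
                              steps = 4e4, p_ext = 1e-4, n_record = 300,
                              t_m_ms = 100, n_rep = 1) {
  stopifnot(inherits(targets, "match_targets"))
  rows <- list()
  for (p_s in p_s_grid) for (bp in bp_grid) {
    if (bp <= p_s) next
    cfg <- lattice_config(L = L, variant = "spatial", p_s = p_s, bp = bp,
                          p_ext = p_ext, steps = steps)
    fit <- tryCatch(
      fit_double_exponential(replicate_unit_ac(cfg, n_rep, n_record,
                                               t_m_ms + 50),
                             t_m_ms = t_m_ms),
      error = function(e) list(tau1 = NA_real_, tau2 = NA_real_,
                               c1 = NA_real_, degenerate = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      p_s = p_s, p_r = (bp - p_s) / 8, bp = bp,
      tau1 = fit$tau1, tau2 = fit$tau2, c1 = fit$c1,
      degenerate = fit$degenerate,
      accepted = !fit$degenerate &&
        fit$tau1 >= targets$tau1[1] && fit$tau1 <= targets$tau1[2] &&
        fit$tau2 >= targets$tau2[1] && fit$tau2 <= targets$tau2[2])
  }
  out <- do.call(rbind, rows)
  if (!any(out$accepted)) {
    miss <- abs(out$tau1 - targets$tau1_mean) / targets$tau1_mean +
      abs(out$tau2 - targets$tau2_mean) / targets$tau2_mean
    out$nearest_miss <- seq_len(nrow(out)) == which.min(miss)
  }
  class(out) <- c("match_grid", class(out))
  out
}

# unit-averaged AC averaged over n_rep independent runs of the same config
replicate_unit_ac <- function(cfg, n_rep, n_record, max_lag_ms) {
  acs <- lapply(seq_len(n_rep), function(r) {
    run <- simulate_lattice(cfg, record = "auto", n_record = n_record)
    unit_autocorrelation(run, max_lag_ms)
  })
  average_correlations(acs)
}

#' Refine a grid search into one operating point per condition
#'
#' Near criticality the coarse-grid timescale estimates carry enough noise
#' that the single point whose estimate looks closest to the target band can
#' have a true slow timescale well outside it (selection noise). This
#' second stage takes the few candidate grid points whose fast timescale is
#' in band and whose slow-timescale estimate is nearest the band center,
#' re-simulates each at higher precision (replicate-averaged long runs),
#' and returns the candidate whose refined fit lands closest to the band
#' center, together with that refined fit — which is then also the
#' operating point's reported timescale estimate.
#'
#' @param grid a `match_grid` from [grid_search_match()].
#' @param targets the condition's [match_targets()].
#' @param p_s restrict candidates to this self-excitation value (use to
#'   force a shared p_s across conditions, i.e. a p_r-only scenario).
#' @param n_candidates grid points re-simulated (default 2).
#' @param L,steps,n_rep,n_record,t_m_ms,p_ext refinement simulation and fit
#'   settings.
#' @return List with `point` (the chosen grid row) and `fit` (the refined
#'   `double_exp_fit`).
#' @export
match_operating_point <- function(grid, targets, p_s = NULL,
                                  n_candidates = 2, L = 50, steps = 1e5,
                                  n_rep = 4, n_record = 300, t_m_ms = 100,
                                  p_ext = 1e-4) {
  cand <- grid[!grid$degenerate & !is.na(grid$tau2), , drop = FALSE]
  if (!is.null(p_s)) cand <- cand[cand$p_s == p_s, , drop = FALSE]
  in1 <- cand$tau1 >= targets$tau1[1] & cand$tau1 <= targets$tau1[2]
  if (any(in1)) cand <- cand[in1, , drop = FALSE]
  if (nrow(cand) == 0) stop("no viable candidate grid point")
  cand <- cand[order(abs(cand$tau2 - targets$tau2_mean)), , drop = FALSE]
  cand <- cand[seq_len(min(n_candidates, nrow(cand))), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    cfg <- lattice_config(L = L, variant = "spatial", p_s = cand$p_s[i],
                          p_r = cand$p_r[i], p_ext = p_ext, steps = steps)
    fit <- tryCatch(
      fit_double_exponential(replicate_unit_ac(cfg, n_rep, n_record,
                                               t_m_ms + 50),
                             t_m_ms = t_m_ms),
      error = function(e) NULL)
    if (is.null(fit)) next
    score <- abs(fit$tau2 - targets$tau2_mean)
    if (is.null(best) || score < best$score)
      best <- list(point = cand[i, ], fit = fit, score = score)
  }
  if (is.null(best)) stop("refinement fits failed for all candidates")
  best
}

# pick the accepted grid point whose timescales sit closest to the band
# centers (relative error); used to select one operating point per condition
best_accepted_point <- function(grid, targets) {
  acc <- grid[grid$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted grid point; see nearest_miss")
  score <- abs(acc$tau1 - targets$tau1_mean) / targets$tau1_mean +
    abs(acc$tau2 - targets$tau2_mean) / targets$tau2_mean
  acc[which.min(score), ]
}

#' Compare attention-condition operating points of the network
#'
#' Simulates the network at an attend-away and an attend-in operating point
#' (typically selected by [grid_search_match()] against the two conditions'
#' timescale bands), fits both autocorrelations, and reports the change in
#' each timescale, the percent change of the slow timescale, and which
#' parameter(s) differ (p_r-only, p_s-only, or compensated).
#'
#' @param params_away,params_in lists (or one-row data.frames) with `p_s`
#'   and `p_r`.
#' @param L,steps,p_ext,n_record,t_m_ms simulation and fit settings (longer
#'   than the search defaults for precise final estimates).
#' @param n_rep replicate simulations averaged per operating point.
#' @return List with the two fits, `delta_tau1`, `delta_tau2`,
#'   `pct_change_tau2` and `scenario`.
#' @export
attention_scenarios <- function(params_away, params_in, L = 50,
                                steps = 1e5, p_ext = 1e-4, n_record = 300,
                                t_m_ms = 100, n_rep = 1) {
  fits <- lapply(list(away = params_away, in_ = params_in), function(p) {
    cfg <- lattice_config(L = L, variant = "spatial", p_s = p$p_s,
                          p_r = p$p_r, p_ext = p_ext, steps = steps)
    fit_double_exponential(replicate_unit_ac(cfg, n_rep, n_record,
                                             t_m_ms + 50),
                           t_m_ms = t_m_ms)
  })
  same_ps <- isTRUE(all.equal(params_away$p_s, params_in$p_s))
  same_pr <- isTRUE(all.equal(params_away$p_r, params_in$p_r))
  scenario <- if (same_ps && same_pr) "identical"
    else if (same_ps) "p_r-only" else if (same_pr) "p_s-only"
    else "compensated"
  list(fit_away = fits$away, fit_in = fits$in_,
       delta_tau1 = fits$in_$tau1 - fits$away$tau1,
       delta_tau2 = fits$in_$tau2 - fits$away$tau2,
       pct_change_tau2 = 100 * (fits$in_$tau2 / fits$away$tau2 - 1),
       scenario = scenario)
}
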