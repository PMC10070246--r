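#' Map discrete transition probabilities to continuous rates
#'
#' The discrete-time binary-unit model with self-excitation `p_s`, recurrent
#' excitation `p_r` and external drive `p_ext` corresponds to a
#' continuous-time rate model with two non-interaction rates (alpha1 for
#' spontaneous activation, alpha2 for deactivation) and equal interaction
#' rates beta1 = beta2. The common conversion factor is
#' -log(p_s) / ((1 - p_s) dt), and alpha1 + alpha2 = -log(p_s)/dt exactly.
#'
#' @param p_s self-excitation probability, in (0, 1).
#' @param p_r recurrent excitation probability per active neighbor.
#' @param p_ext external excitation probability.
#' @param dt_ms time-step duration (default 1 ms).
#' @return List with `alpha1`, `alpha2`, `beta1`, `beta2` (per ms) and `dt_ms`.
#' @export
map_discrete_to_rates <- function(p_s, p_r, p_ext, dt_ms = 1) {
  if (p_s <= 0 || p_s >= 1) stop("p_s must be strictly inside (0, 1)")
  fac <- -log(p_s) / ((1 - p_s) * dt_ms)
  out <- list(alpha1 = p_ext * fac,
              alpha2 = (1 - p_s - p_ext) * fac,
              beta1 = p_r * fac, beta2 = p_r * fac, dt_ms = dt_ms)
  stopifnot(abs(out$alpha1 + out$alpha2 - (-log(p_s) / dt_ms)) <
              1e-10 * abs(log(p_s) / dt_ms))
  out
}

#' Steady-state mean activity of the linear network
#'
#' p_ext / (1 - (p_s + n p_r)); diverges at the critical branching
#' parameter BP = p_s + n p_r = 1.
#'
#' @inheritParams map_discrete_to_rates
#' @param n in-degree (default 8).
#' @export
steady_state_activity <- function(p_s, p_r, p_ext, n = 8) {
  bp <- p_s + n * p_r
  if (bp >= 1) stop("branching parameter >= 1: no finite steady state")
  p_ext / (1 - bp)
}

#' Self-excitation timescale
#'
#' Autocorrelation decay constant of an isolated two-state Markov unit:
#' -dt / log(p_s).
#'
#' @inheritParams map_discrete_to_rates
#' @export
tau_self <- function(p_s, dt_ms = 1) {
  if (any(p_s <= 0 | p_s >= 1)) stop("p_s must be strictly inside (0, 1)")
  -dt_ms / log(p_s)
}

#' Autocorrelation of the two-state Markov unit
#'
#' p_s^t at integer lag t (in steps): the exact autocorrelation of a unit
#' driven only by self-excitation and weak external input.
#'
#' @param p_s self-excitation probability.
#' @param t non-negative integer lag(s), in steps.
#' @export
markov_ac <- function(p_s, t) {
  stopifnot(all(t >= 0))
  p_s^t
}

#' Interaction timescale of a spatial-frequency mode
#'
#' Timescale of the correlated-fluctuation mode at spatial frequency
#' (k1, k2) in the locally connected network:
#' tau_self / (1 - (n/4) (p_r/(1-p_s)) (cos k1 + cos k2 + 2 cos k1 cos k2)).
#' At k = (0, 0) this reduces exactly to the global timescale.
#'
#' @inheritParams map_discrete_to_rates
#' @param k1,k2 spatial frequencies in radians.
#' @param n in-degree (default 8).
#' @export
tau_int_k <- function(p_s, p_r, k1, k2, dt_ms = 1, n = 8) {
  ratio <- p_r / (1 - p_s)            # beta1 / (alpha1 + alpha2)
  den <- 1 - (n / 4) * ratio * (cos(k1) + cos(k2) + 2 * cos(k1) * cos(k2))
  if (any(den <= 0)) stop("mode denominator <= 0 (supercritical parameters)")
  tau_self(p_s, dt_ms) / den
}

#' Global interaction timescale
#'
#' The k = 0 mode: -dt (1 - p_s) / ((1 - p_s - n p_r) log(p_s)). Diverges
#' monotonically as BP -> 1.
#'
#' @inheritParams tau_int_k
#' @export
tau_global <- function(p_s, p_r, dt_ms = 1, n = 8) {
  bp <- p_s + n * p_r
  if (any(bp >= 1)) stop("branching parameter >= 1: global timescale diverges")
  -dt_ms * (1 - p_s) / ((1 - p_s - n * p_r) * log(p_s))
}

#' Spatial-frequency mode grid
#'
#' The mode grid used by the analytical autocorrelation: k = 2 pi j / L for
#' j = 0 .. L/2 - 1 in each dimension (L^2/4 modes).
#'
#' @param L lattice side (even).
#' @export
mode_grid <- function(L) {
  stopifnot(L %% 2 == 0)
  k <- 2 * pi * (0:(L / 2 - 1)) / L
  expand.grid(k1 = k, k2 = k)
}

#' Interaction-timescale spectrum
#'
#' Mode timescales over the grid from [mode_grid()], optionally with
#' weights (relative cross-correlation amplitudes per mode) attached.
#'
#' @inheritParams tau_int_k
#' @param L lattice side.
#' @param weights optional numeric vector aligned with the grid rows.
#' @return data.frame with columns k1, k2, tau_ms (and weight).
#' @export
timescale_spectrum <- function(p_s, p_r, L, dt_ms = 1, n = 8,
                               weights = NULL) {
  g <- mode_grid(L)
  g$tau_ms <- tau_int_k(p_s, p_r, g$k1, g$k2, dt_ms, n)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(g))
    g$weight <- weights
  }
  g
}

#' Effective interaction timescale
#'
#' Weighted average of the interaction timescales over the spatial-frequency
#' modes, with weights given by the relative cross-correlation amplitude of
#' each mode. This single timescale approximates the slow decay of the
#' unit autocorrelation.
#'
#' @param spectrum data.frame with columns `tau_ms` and `weight` (from
#'   [timescale_spectrum()] with weights).
#' @export
tau_int_effective <- function(spectrum) {
  stopifnot(nrow(spectrum) > 0, !is.null(spectrum$weight))
  w <- spectrum$weight
  if (sum(w) <= 0) stop("mode weights must have positive sum")
  sum(w * spectrum$tau_ms) / sum(w)
}

#' Mode weights from an equal-time spatial covariance map
#'
#' Estimates the relative cross-correlation amplitude of each
#' spatial-frequency mode as the 2-D discrete Fourier transform of the
#' equal-time spatial covariance. The zero-offset entry of the covariance
#' map mixes the uncorrelated (self) variance with the interaction
#' covariance; it is replaced by an exponential-in-distance extrapolation
#' of the d = 1..3 Chebyshev shells before transforming, so the weights
#' reflect the interaction component only. Amplitudes are read on the
#' L/2 x L/2 quarter grid (one representative per mirror-symmetric mode
#' family, matching the mode-grid convention). Small negative Fourier
#' amplitudes (estimation noise) are clipped to zero.
#'
#' @param cov_map L x L matrix of circular spatial covariances, entry
#'   `[1 + dx, 1 + dy]` being the covariance at lattice offset (dx, dy)
#'   (e.g. from [spatial_covariance()]).
#' @return List with `weights` (aligned with [mode_grid()] of the same L),
#'   `interaction_var0` (extrapolated interaction covariance at zero
#'   offset) and `total_var` (the raw zero-offset variance).
#' @export
mode_weights <- function(cov_map) {
  L <- nrow(cov_map)
  stopifnot(ncol(cov_map) == L, L %% 2 == 0)
  total_var <- cov_map[1, 1]
  if (total_var <= 0) stop("covariance at zero offset must be positive")
  # Chebyshev shell means at d = 1..3 for the zero-offset extrapolation
  dx <- pmin(0:(L - 1), L - (0:(L - 1)))
  cheb <- outer(dx, dx, pmax)
  shell <- vapply(1:3, function(d) mean(cov_map[cheb == d]), numeric(1))
  c0 <- if (all(shell > 0)) {
    exp(stats::lm(log(shell) ~ I(1:3))$coefficients[[1]])  # value at d = 0
  } else total_var   # no short-range structure: keep the raw variance,
                     # which yields uniform (spatially white) mode weights
  c0 <- min(c0, total_var)              # cannot exceed the total variance
  cm <- cov_map
  cm[1, 1] <- c0
  W <- Re(stats::fft(cm))               # interaction amplitude per mode
  W[W < 0] <- 0
  half <- L / 2                         # quarter grid: one mode per (k1, k2)
  list(weights = as.vector(W[1:half, 1:half]), interaction_var0 = c0,
       total_var = total_var)
}

#' Analytical unit autocorrelation of the spatial network
#'
#' Normalized mixture of the self-excitation decay and the weighted
#' interaction-mode decays: AC(t) = A exp(-t/tau_self) +
#' sum_k w_k exp(-t/tau_k) with A chosen so that AC(0) = 1. Weights are
#' interpreted as fractions of the unit variance carried by each
#' interaction mode (so sum(w) must be < 1).
#'
#' @inheritParams tau_int_k
#' @param L lattice side.
#' @param weights interaction-mode weights aligned with [mode_grid()] rows,
#'   as variance fractions.
#' @param t_ms lag grid in ms.
#' @return A `corr_function`.
#' @export
ac_analytic <- function(p_s, p_r, L, weights, t_ms, dt_ms = 1, n = 8) {
  spec <- timescale_spectrum(p_s, p_r, L, dt_ms, n, weights)
  W <- sum(spec$weight)
  if (W >= 1) stop("interaction weights must sum to less than 1")
  A <- 1 - W
  vals <- A * exp(-t_ms / tau_self(p_s, dt_ms))
  # group modes by timescale to keep the sum cheap on large grids
  agg <- stats::aggregate(weight ~ tau_ms, spec, sum)
  for (r in seq_len(nrow(agg)))
    vals <- vals + agg$weight[r] * exp(-t_ms / agg$tau_ms[r])
  corr_function(t_ms, vals, "auto", 1L, dt_ms)
}

#' Effective parameters and timescales under nonlinear interactions
#'
#' For multiplicative (nonlinear) recurrent coupling with activation
#' function F(x) = 1 - exp(-theta x / n) and a constant global input
#' current I, the mean activity and the effective transition rates are
#' found self-consistently: S_bar solves
#' S = (alpha1 + beta1' F(nS + I)) / (alpha1 + alpha2 + (beta1'-beta2') F(nS + I)),
#' after which the linearized interaction rates are
#' beta_i = beta_i' F'(n S_bar + I), the effective non-interaction rates are
#' alpha1 + beta1' F0 and alpha2 - beta2' F0 with
#' F0 = F(nS+I) - nS F'(nS+I), and the self-excitation and global
#' timescales follow as 1/(alpha1_eff + alpha2_eff) and its renormalization
#' by the interaction gain. When beta1' < beta2', increasing I raises the
#' mean activity and the self-excitation timescale; if additionally
#' -|beta1'-beta2'| S_bar + beta1' < 0, the global timescale also grows.
#'
#' @param alpha1,alpha2 non-interaction rates (per ms), e.g. from
#'   [map_discrete_to_rates()].
#' @param beta1p,beta2p bare interaction rates (per ms). To emulate the
#'   linear model with interaction rate beta, use beta * n / theta with
#'   small theta.
#' @param theta gain of the recurrent nonlinearity (> 0).
#' @param input_I constant global input current (>= 0).
#' @param n in-degree (default 8).
#' @param tol,max_iter,damping fixed-point iteration controls.
#' @return List: `S_bar`, effective rates, linearized `beta1`/`beta2`,
#'   `tau_self_ms`, `tau_global_ms`, and the sign conditions
#'   `self_increases_with_I`, `global_increases_with_I`.
#' @export
nonlinear_effective_params <- function(alpha1, alpha2, beta1p, beta2p,
                                       theta, input_I = 0, n = 8,
                                       tol = 1e-10, max_iter = 1e4,
                                       damping = 0.5) {
  stopifnot(theta > 0, input_I >= 0, alpha1 >= 0, alpha2 > 0)
  Ffun <- function(S) 1 - exp(-theta * S - input_I)
  S <- alpha1 / (alpha1 + alpha2)       # linear-model starting point
  for (i in seq_len(max_iter)) {
    Fv <- Ffun(S)
    S_new <- (alpha1 + beta1p * Fv) /
      (alpha1 + alpha2 + (beta1p - beta2p) * Fv)
    S_new <- min(max(S_new, 0), 1)
    if (abs(S_new - S) < tol) { S <- S_new; break }
    S <- damping * S_new + (1 - damping) * S
    if (i == max_iter) stop("mean-activity fixed point did not converge")
  }
  e <- exp(-theta * S - input_I)
  Fp <- (theta / n) * e                 # dF/dx at x = n S_bar (+ I)
  F0 <- 1 - (theta * S + 1) * e
  beta1 <- beta1p * Fp; beta2 <- beta2p * Fp
  a1e <- alpha1 + beta1p * F0
  a2e <- alpha2 - beta2p * F0
  if (a1e + a2e <= 0) stop("effective rates non-positive; outside validity")
  ts <- 1 / (a1e + a2e)
  gden <- 1 - n * beta1 / (a1e + a2e)
  if (gden <= 0) stop("supercritical effective parameters")
  list(S_bar = S, alpha1_eff = a1e, alpha2_eff = a2e,
       beta1 = beta1, beta2 = beta2, F0 = F0,
       tau_self_ms = ts, tau_global_ms = ts / gden,
       self_increases_with_I = (beta1p - beta2p) < 0,
       global_increases_with_I = (beta1p - beta2p) < 0 &&
         (-abs(beta1p - beta2p) * S + beta1p) < 0)
}
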