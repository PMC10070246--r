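#' Configuration of a binary-unit lattice network
#'
#' Units live on an L x L square lattice with periodic boundaries; each unit
#' receives input from exactly 8 others. Connectivity variants: `"spatial"`
#' (Moore neighborhood), `"dispersed"` (8 random partners within Chebyshev
#' radius `r`), `"random"` (8 random partners anywhere), `"two_type"` (two
#' units per node, types A and B with their own self-excitation, random
#' connectivity across both types) and `"synaptic"` (random connectivity
#' with a low-pass filter of time constant `tau_synapse` on the recurrent
#' input). The update rule is `"linear"` (additive transition probabilities)
#' or `"nonlinear"` (multiplicative); the synaptic variant always uses the
#' linear rule on the filtered input.
#'
#' @param L lattice side (default 100).
#' @param variant connectivity/mechanism variant.
#' @param rule interaction rule.
#' @param p_s self-excitation probability; length 2 (A, B) for `two_type`.
#' @param p_r recurrent probability per active neighbor; derived from `bp`
#'   when `bp` is given (p_r = (bp - p_s)/8, per type for `two_type`).
#' @param bp branching parameter p_s + 8 p_r (optional shorthand).
#' @param p_ext external excitation probability (default 1e-4).
#' @param tau_synapse synaptic filter time constant in steps (synaptic
#'   variant; default 41).
#' @param r connectivity radius for the dispersed variant.
#' @param steps recorded simulation steps (default 1e5).
#' @param dt_ms duration of one step (default 1 ms).
#' @return A `lattice_config`.
#' @export
lattice_config <- function(L = 100,
                           variant = c("spatial", "dispersed", "random",
                                       "two_type", "synaptic"),
                           rule = c("linear", "nonlinear"),
                           p_s = 0.88, p_r = NULL, bp = NULL,
                           p_ext = 1e-4, tau_synapse = 41, r = 1,
                           steps = 1e5, dt_ms = 1) {
  variant <- match.arg(variant); rule <- match.arg(rule)
  if (variant == "two_type" && length(p_s) != 2)
    stop("two_type variant needs p_s = c(A, B)")
  if (is.null(p_r)) {
    if (is.null(bp)) stop("give either p_r or bp")
    p_r <- (bp - p_s) / 8
  }
  if (length(p_r) != length(p_s)) p_r <- rep(p_r, length(p_s))
  if (any(p_r < 0) || any(p_s < 0 | p_s >= 1) || p_ext < 0 || p_ext > 1)
    stop("probabilities out of range")
  if (variant == "dispersed" && (r < 1 || L < 2 * r + 1))
    stop("infeasible connectivity radius")
  if (variant == "synaptic" && tau_synapse < dt_ms)
    stop("tau_synapse must be at least one step")
  structure(list(L = as.integer(L), variant = variant, rule = rule,
                 p_s = p_s, p_r = p_r, bp = p_s + 8 * p_r, p_ext = p_ext,
                 tau_synapse = tau_synapse, r = as.integer(r),
                 steps = as.integer(steps), dt_ms = dt_ms),
            class = "lattice_config")
}

# lattice position helpers (1-based unit index <-> (row, col), row-major)
lattice_pos <- function(idx, L) cbind(row = (idx - 1L) %/% L, col = (idx - 1L) %% L)
lattice_idx <- function(row, col, L) (row %% L) * L + (col %% L) + 1L

#' Build the in-edge connectivity of a lattice network
#'
#' Returns an n x 8 matrix of presynaptic unit indices (1-based). Every unit
#' has in-degree exactly 8 and no self-loops; dispersed partners are all
#' within Chebyshev radius `r` (with periodic wrap); the random variant
#' draws partners from the whole lattice. For `two_type`, n = 2 L^2 (units
#' 1..L^2 are type A, the rest type B at the same nodes) and partners are
#' drawn from all units of any type.
#'
#' @param cfg a `lattice_config`.
#' @export
build_connectivity <- function(cfg) {
  L <- cfg$L; n_nodes <- L * L
  if (cfg$variant == "spatial" ||
      (cfg$variant == "dispersed" && cfg$r == 1)) {
    off <- expand.grid(dr = -1:1, dc = -1:1)
    off <- off[!(off$dr == 0 & off$dc == 0), ]
    pos <- lattice_pos(seq_len(n_nodes), L)
    adj <- sapply(seq_len(8), function(j)
      lattice_idx(pos[, "row"] + off$dr[j], pos[, "col"] + off$dc[j], L))
    return(matrix(as.integer(adj), n_nodes, 8))
  }
  if (cfg$variant == "dispersed") {
    d <- -cfg$r:cfg$r
    off <- expand.grid(dr = d, dc = d)
    off <- off[!(off$dr == 0 & off$dc == 0), ]
    pos <- lattice_pos(seq_len(n_nodes), L)
    adj <- matrix(0L, n_nodes, 8)
    for (i in seq_len(n_nodes)) {
      pick <- sample.int(nrow(off), 8)
      adj[i, ] <- lattice_idx(pos[i, "row"] + off$dr[pick],
                              pos[i, "col"] + off$dc[pick], L)
    }
    return(adj)
  }
  n <- if (cfg$variant == "two_type") 2L * n_nodes else n_nodes
  adj <- matrix(0L, n, 8)
  for (i in seq_len(n)) {
    p <- sample.int(n - 1L, 8)
    adj[i, ] <- ifelse(p >= i, p + 1L, p)    # skip self
  }
  adj
}

#' One synchronous update step (pure-R reference)
#'
#' Applies the transition probabilities of the chosen rule to every unit
#' from the previous state. Kept as a readable reference implementation for
#' small systems and for checking the compiled simulator; use
#' [simulate_lattice()] for long runs.
#'
#' @param state 0/1 vector.
#' @param adj n x 8 in-edge matrix (1-based).
#' @param cfg a `lattice_config` (per-unit p_s/p_r expanded as in
#'   [simulate_lattice()]).
#' @return New 0/1 state vector.
#' @export
step_lattice <- function(state, adj, cfg) {
  p <- transition_probabilities(state, adj, cfg)
  as.integer(stats::runif(length(state)) < p)
}

#' Per-unit activation probabilities for the next step
#'
#' For the linear rule an inactive unit activates with probability
#' p_ext + p_r * (active in-neighbors) and an active one persists with
#' probability p_ext + p_s + p_r * (active in-neighbors) (clipped to
#' `[0, 1]`); the nonlinear rule multiplies the per-input failure
#' probabilities instead. Exposed for direct frequency tests of the update
#' rule.
#'
#' @inheritParams step_lattice
#' @return Vector of probabilities that each unit is active at t + 1.
#' @export
transition_probabilities <- function(state, adj, cfg) {
  n <- length(state)
  if (cfg$variant == "two_type") {      # per-type parameters, node-major
    half <- cfg$L^2
    stopifnot(n == 2 * half)
    ps <- c(rep(cfg$p_s[1], half), rep(cfg$p_s[2], half))
    pr <- c(rep(cfg$p_r[1], half), rep(cfg$p_r[2], half))
  } else {
    ps <- rep(cfg$p_s, n); pr <- rep(cfg$p_r, n)
  }
  nact <- rowSums(matrix(state[adj], nrow = n))
  if (cfg$rule == "nonlinear") {
    q <- (1 - pr)^nact
    ifelse(state == 1,
           1 - (1 - cfg$p_ext) * (1 - ps) * q,
           1 - (1 - cfg$p_ext) * q)
  } else {
    pmin(pmax(cfg$p_ext + pr * nact + ifelse(state == 1, ps, 0), 0), 1)
  }
}

#' Simulate a lattice network
#'
#' Runs the compiled synchronous simulator. The initial state draws every
#' unit active with the analytic steady-state probability; a burn-in of
#' 10 predicted global timescales (by default) is discarded before
#' recording. Histories are recorded for a subset of units (all units for
#' small systems) to keep memory bounded; the pooled network activity is
#' always recorded in full.
#'
#' @param cfg a `lattice_config`.
#' @param record `"auto"` (all units when L <= 60, else a random sample of
#'   `n_record`), `"all"`, or an integer vector of unit indices.
#' @param n_record subsample size for `record = "auto"`.
#' @param n_shadow number of passive shadow units (attached to the first
#'   `n_shadow` units; driven only by their recurrent input, no feedback).
#' @param burnin discarded steps (default 10 x predicted global timescale).
#' @return A `lattice_run`: raw state histories of the recorded units (and
#'   shadow units), pooled activity, recorded positions, realized mean
#'   activity and the clip counter.
#' @export
simulate_lattice <- function(cfg, record = "auto", n_record = 300,
                             n_shadow = 0, burnin = NULL) {
  stopifnot(inherits(cfg, "lattice_config"))
  adj <- build_connectivity(cfg)
  n <- nrow(adj)
  if (cfg$variant == "two_type") {
    half <- cfg$L^2
    ps <- c(rep(cfg$p_s[1], half), rep(cfg$p_s[2], half))
    pr <- c(rep(cfg$p_r[1], half), rep(cfg$p_r[2], half))
  } else {
    ps <- rep(cfg$p_s, n); pr <- rep(cfg$p_r, n)
  }
  bp <- max(cfg$bp)
  sbar <- if (bp < 1) cfg$p_ext / (1 - bp) else 0.5
  if (is.null(burnin)) {
    tg <- if (bp < 1 && min(cfg$p_s) > 0)
      max(tau_global(min(cfg$p_s), (bp - min(cfg$p_s)) / 8, cfg$dt_ms))
      else 100
    burnin <- as.integer(min(10 * ceiling(tg), 2e4))
  }
  if (identical(record, "auto")) {
    rec_idx <- if (n <= 3600) seq_len(n) else sort(sample.int(n, min(n_record, n)))
  } else if (identical(record, "all")) {
    rec_idx <- seq_len(n)
  } else rec_idx <- as.integer(record)
  init <- as.integer(stats::runif(n) < sbar)
  rule_code <- if (cfg$variant == "synaptic") 2L
               else switch(cfg$rule, linear = 0L, nonlinear = 1L)
  res <- cpp_lattice_simulate(ps, pr, cfg$p_ext, adj - 1L, rule_code,
                              cfg$tau_synapse / cfg$dt_ms,
                              cfg$steps, burnin, init, rec_idx - 1L,
                              as.integer(n_shadow))
  node_idx <- (rec_idx - 1L) %% (cfg$L^2) + 1L
  structure(list(cfg = cfg, record = res$record, shadow = res$shadow,
                 pooled = res$pooled, record_idx = rec_idx,
                 positions = lattice_pos(node_idx, cfg$L),
                 mean_activity = res$mean_activity,
                 clip_count = res$clip_count, burnin = burnin),
            class = "lattice_run")
}

#' @export
print.lattice_run <- function(x, ...) {
  cat(sprintf("<lattice_run> %s/%s, L=%d, %d steps, mean activity %.4g\n",
              x$cfg$variant, x$cfg$rule, x$cfg$L, x$cfg$steps,
              x$mean_activity))
  invisible(x)
}

# raw 0/1 history matrix of the recorded units, pooling A+B per node for the
# two-type variant (pooled values 0/1/2 still fit in a raw byte)
run_history <- function(run) {
  rec <- run$record
  if (run$cfg$variant == "two_type") {
    half <- run$cfg$L^2
    a <- run$record_idx <= half
    ia <- which(a); ib <- which(!a)
    node_a <- run$record_idx[ia]; node_b <- run$record_idx[ib] - half
    common <- intersect(node_a, node_b)
    if (length(common) == 0) stop("no node with both unit types recorded")
    ma <- rec[ia[match(common, node_a)], , drop = FALSE]
    mb <- rec[ib[match(common, node_b)], , drop = FALSE]
    rec <- matrix(as.raw(as.integer(ma) + as.integer(mb)),
                  nrow = length(common))
  }
  rec
}

#' Unit-averaged long-run autocorrelation of a lattice run
#'
#' Single-long-window estimator (no windowing bias) averaged over the
#' recorded units; constant units are excluded. For the two-type variant
#' the summed A + B activity per node is used.
#'
#' @param run a `lattice_run`.
#' @param max_lag_ms maximum lag (ms).
#' @return A `corr_function` (with attribute `n_units`).
#' @export
unit_autocorrelation <- function(run, max_lag_ms = 150) {
  ml <- as.integer(max_lag_ms / run$cfg$dt_ms)
  res <- cpp_unit_ac(run_history(run), ml)
  if (res$n_units == 0) stop("all recorded units have zero variance")
  cf <- corr_function((0:ml) * run$cfg$dt_ms, res$ac, "auto",
                      n_windows = 1L, bin_ms = run$cfg$dt_ms)
  attr(cf, "n_units") <- res$n_units
  cf
}

#' Autocorrelation of the pooled network activity
#' @inheritParams unit_autocorrelation
#' @export
global_autocorrelation <- function(run, max_lag_ms = 500) {
  ml <- as.integer(max_lag_ms / run$cfg$dt_ms)
  corr_function((0:ml) * run$cfg$dt_ms, cpp_series_ac(run$pooled, ml),
                "auto", 1L, run$cfg$dt_ms)
}

#' Autocorrelation of the recurrent input (shadow units)
#'
#' Averages the long-run autocorrelations of the passive shadow units,
#' which see only the horizontal recurrent input of their host unit. Their
#' decay isolates the interaction component of the unit autocorrelation.
#'
#' @inheritParams unit_autocorrelation
#' @export
shadow_autocorrelation <- function(run, max_lag_ms = 150) {
  if (nrow(run$shadow) == 0) stop("run has no shadow units")
  ml <- as.integer(max_lag_ms / run$cfg$dt_ms)
  res <- cpp_unit_ac(run$shadow, ml)
  if (res$n_units == 0)
    stop("all shadow units silent (is p_r > 0?)")
  cf <- corr_function((0:ml) * run$cfg$dt_ms, res$ac, "auto", 1L,
                      run$cfg$dt_ms)
  attr(cf, "n_units") <- res$n_units
  cf
}

#' Distance-resolved cross-correlations on the lattice
#'
#' Mean cross-correlation between recorded unit pairs at each Chebyshev
#' distance (with periodic wrap), using up to `n_pairs` randomly selected
#' pairs per distance (all available pairs when fewer exist).
#'
#' @param run a `lattice_run`.
#' @param distances Chebyshev distances to evaluate.
#' @param n_pairs pairs sampled per distance.
#' @param max_lag_ms maximum lag (ms).
#' @return List: `cc` (named list of `corr_function`s per distance),
#'   `zero_lag` (data.frame distance / mean zero-lag CC / n_pairs).
#' @export
cc_by_distance <- function(run, distances = 1:5, n_pairs = 4e4,
                           max_lag_ms = 50) {
  hist <- run_history(run)
  pos <- run$positions
  if (run$cfg$variant == "two_type") {
    half <- run$cfg$L^2
    node <- (run$record_idx[run$record_idx <= half])
    node <- intersect(node, run$record_idx[run$record_idx > half] - half)
    pos <- lattice_pos(node, run$cfg$L)
  }
  L <- run$cfg$L
  m <- nrow(pos)
  dr <- abs(outer(pos[, "row"], pos[, "row"], "-")); dr <- pmin(dr, L - dr)
  dc <- abs(outer(pos[, "col"], pos[, "col"], "-")); dc <- pmin(dc, L - dc)
  dch <- pmax(dr, dc)
  ml <- as.integer(max_lag_ms / run$cfg$dt_ms)
  cc <- list(); zl <- data.frame()
  for (d in distances) {
    sel <- which(dch == d & upper.tri(dch), arr.ind = TRUE)
    if (nrow(sel) == 0) next
    if (nrow(sel) > n_pairs) sel <- sel[sample.int(nrow(sel), n_pairs), ,
                                        drop = FALSE]
    res <- cpp_pair_cc(hist, sel[, 1] - 1L, sel[, 2] - 1L, ml)
    if (res$n_pairs == 0) next
    cc[[as.character(d)]] <- corr_function((0:ml) * run$cfg$dt_ms,
                                           res$mean_cc, "cross",
                                           res$n_pairs, run$cfg$dt_ms)
    zl <- rbind(zl, data.frame(distance = d, cc0 = res$mean_cc[1],
                               n_pairs = res$n_pairs))
  }
  list(cc = cc, zero_lag = zl)
}

#' Equal-time spatial covariance map of a full-lattice run
#'
#' Circular covariance between units at every lattice offset, estimated by
#' averaging spatial power spectra over time (requires all units recorded).
#' Entry `[1 + dx, 1 + dy]` is the covariance at offset (dx, dy).
#'
#' @param run a `lattice_run` with `record = "all"`.
#' @param thin use every `thin`-th time step (covariances are smooth in
#'   time; thinning cuts the FFT cost).
#' @export
spatial_covariance <- function(run, thin = 1L) {
  L <- run$cfg$L; n <- L * L
  if (nrow(run$record) != n)
    stop("spatial covariance needs a full-lattice recording")
  X <- run$record
  steps <- ncol(X)
  use <- seq(1L, steps, by = thin)
  mu <- matrix(rowMeans(matrix(as.integer(X), nrow = n)), L, L)
  P <- matrix(0, L, L)
  for (t in use) {
    m <- matrix(as.integer(X[, t]), L, L) - mu
    Fm <- stats::fft(m)
    P <- P + Re(Fm * Conj(Fm))
  }
  Re(stats::fft(P / (length(use) * n), inverse = TRUE)) / n
}
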