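test_that("connectivity builders give in-degree 8, no self-loops, correct support", {
  set.seed(40)
  cfg <- lattice_config(L = 10, variant = "spatial", p_s = 0.8, p_r = 0.01,
                        steps = 10)
  adj <- build_connectivity(cfg)
  expect_equal(dim(adj), c(100L, 8L))
  expect_true(all(adj != seq_len(100)))
  # unit at (5, 5) (index 56): exactly its 8 Moore neighbors
  moore <- sort(multitau:::lattice_idx(rep(4:6, each = 3), rep(4:6, 3), 10))
  moore <- setdiff(moore, 56L)
  expect_equal(sort(adj[56, ]), moore)

  # dispersed: all partners within Chebyshev radius r (periodic wrap)
  cfgd <- lattice_config(L = 20, variant = "dispersed", r = 3, p_s = 0.8,
                         p_r = 0.01, steps = 10)
  adjd <- build_connectivity(cfgd)
  pos <- multitau:::lattice_pos(seq_len(400), 20)
  for (i in c(1, 57, 400)) {
    dr <- abs(pos[adjd[i, ], "row"] - pos[i, "row"]); dr <- pmin(dr, 20 - dr)
    dc <- abs(pos[adjd[i, ], "col"] - pos[i, "col"]); dc <- pmin(dc, 20 - dc)
    expect_true(all(pmax(dr, dc) <= 3))
    expect_equal(length(unique(adjd[i, ])), 8L)      # distinct partners
  }
  expect_error(lattice_config(L = 5, variant = "dispersed", r = 3,
                              p_s = 0.8, p_r = 0.01), "radius")

  # two-type: 2 L^2 units, partners from any type
  cfg2 <- lattice_config(L = 6, variant = "two_type", p_s = c(0.8, 0.9),
                         bp = 0.95, steps = 10)
  adj2 <- build_connectivity(cfg2)
  expect_equal(nrow(adj2), 72L)
  expect_true(any(adj2 > 36) && any(adj2 <= 36))
})

test_that("transition probabilities implement the additive and multiplicative rules", {
  cfg <- lattice_config(L = 3, variant = "spatial", p_s = 0.6, p_r = 0.02,
                        p_ext = 1e-3, steps = 10)
  adj <- build_connectivity(cfg)
  state <- rep(0L, 9)
  # all-inactive: activation probability p_ext everywhere (both rules)
  expect_equal(transition_probabilities(state, adj, cfg), rep(1e-3, 9))
  cfgn <- cfg; cfgn$rule <- "nonlinear"
  expect_equal(transition_probabilities(state, adj, cfgn), rep(1e-3, 9))
  # isolated active unit (p_r = 0): persistence p_s + p_ext
  cfg0 <- lattice_config(L = 3, variant = "spatial", p_s = 0.6, p_r = 0,
                         p_ext = 1e-3, steps = 10)
  state[5] <- 1L
  expect_equal(transition_probabilities(state, adj, cfg0)[5], 0.6 + 1e-3)
  # linear rule with k active neighbors: p_ext + p_r k (inactive target)
  state <- rep(0L, 9); state[adj[1, 1:3]] <- 1L
  p <- transition_probabilities(state, adj, cfg)
  k1 <- sum(state[adj[1, ]])
  expect_equal(p[1], 1e-3 + 0.02 * k1)
  # nonlinear rule: 1 - (1-p_ext)(1-p_r)^k
  pn <- transition_probabilities(state, adj, cfgn)
  expect_equal(pn[1], 1 - (1 - 1e-3) * (1 - 0.02)^k1)
  # nonlinear deactivation: (1-p_ext)(1-p_s)(1-p_r)^k
  staten <- state; staten[1] <- 1L
  pn1 <- transition_probabilities(staten, adj, cfgn)[1]
  expect_equal(1 - pn1, (1 - 1e-3) * (1 - 0.6) * (1 - 0.02)^k1)
})

test_that("compiled stepper matches the update rule in logged transition frequencies", {
  # chi-square style check: empirical activation frequencies conditioned on
  # (own state, active in-neighbors) match the analytic probabilities
  set.seed(41)
  cfg <- lattice_config(L = 8, variant = "spatial", p_s = 0.7, p_r = 0.03,
                        p_ext = 0.02, steps = 4000)
  adj <- build_connectivity(cfg)
  run <- simulate_lattice(cfg, record = "all", burnin = 100)
  H <- matrix(as.integer(run$record), nrow = 64)
  nact <- matrix(0L, 64, ncol(H) - 1)
  for (t in seq_len(ncol(H) - 1))
    nact[, t] <- as.integer(rowSums(matrix(H[adj, t], nrow = 64)))
  cur <- H[, -ncol(H)]; nxt <- H[, -1]
  for (s in 0:1) for (k in 0:3) {
    sel <- cur == s & nact == k
    n <- sum(sel)
    if (n < 500) next
    emp <- mean(nxt[sel])
    theo <- min(0.02 + 0.03 * k + s * 0.7, 1)
    expect_lt(abs(emp - theo), 4 * sqrt(theo * (1 - theo) / n))
  }
})

test_that("states stay binary, quiescence is absorbing without drive, runs reproduce", {
  set.seed(42)
  cfg <- lattice_config(L = 10, variant = "spatial", p_s = 0.8, p_r = 0.02,
                        p_ext = 0, steps = 50)
  run <- simulate_lattice(cfg, record = "all", burnin = 0)
  # steady-state init with p_ext = 0 gives the empty configuration: absorbing
  expect_true(all(run$pooled == 0))
  set.seed(43)
  cfg2 <- lattice_config(L = 10, variant = "spatial", p_s = 0.8, p_r = 0.02,
                         p_ext = 0.01, steps = 200)
  r1 <- simulate_lattice(cfg2, record = "all")
  expect_true(all(as.integer(r1$record) %in% 0:1))
  set.seed(43)
  r2 <- simulate_lattice(cfg2, record = "all")
  expect_identical(r1$record, r2$record)
})

test_that("long-run mean activity matches the master-equation steady state", {
  set.seed(44)
  for (bp in c(0.9, 0.97)) {
    cfg <- lattice_config(L = 30, variant = "spatial", p_s = 0.8, bp = bp,
                          p_ext = 5e-4, steps = 2e4)
    run <- simulate_lattice(cfg)
    sbar <- steady_state_activity(0.8, (bp - 0.8) / 8, 5e-4)
    # s.e. of the mean over ~steps/tau_global independent network states
    n_eff <- cfg$steps / tau_global(0.8, (bp - 0.8) / 8) * 30^2 / 50
    se <- sqrt(sbar / n_eff)
    expect_lt(abs(run$mean_activity - sbar), 3 * se + 0.1 * sbar)
  }
})

test_that("isolated units reproduce the two-state Markov autocorrelation", {
  set.seed(45)
  cfg <- lattice_config(L = 20, variant = "spatial", p_s = 0.85, p_r = 0,
                        p_ext = 0.02, steps = 2e4)
  run <- simulate_lattice(cfg)
  ac <- unit_autocorrelation(run, 20)
  expect_lt(max(abs(ac$values - markov_ac(0.85, 0:20))), 0.02)
})

test_that("the synaptic filter tracks its input and reduces to the linear model", {
  set.seed(46)
  # tau_synapse = 1 step: the filter follows the input within one step, so
  # the stationary activity matches the plain linear model
  cfg_lin <- lattice_config(L = 20, variant = "spatial", p_s = 0.8,
                            bp = 0.95, p_ext = 1e-3, steps = 2e4)
  cfg_syn <- lattice_config(L = 20, variant = "synaptic", p_s = 0.8,
                            bp = 0.95, p_ext = 1e-3, tau_synapse = 1,
                            steps = 2e4)
  r_lin <- simulate_lattice(cfg_lin)
  r_syn <- simulate_lattice(cfg_syn)
  expect_equal(r_syn$mean_activity, r_lin$mean_activity, tolerance = 0.15)
  # slow filter: unit AC gains a slow component near tau_synapse
  set.seed(47)
  cfg_s40 <- lattice_config(L = 30, variant = "synaptic", p_s = 0.8,
                            bp = 0.97, p_ext = 1e-3, tau_synapse = 30,
                            steps = 3e4)
  ac <- unit_autocorrelation(simulate_lattice(cfg_s40), 100)
  tail_tau <- fit_exponential(ac, t_m_ms = 100, min_lag_ms = 40,
                              tau_start = 30)$tau
  expect_gt(tail_tau, 15)                            # far above tau_self = 4.5
})

test_that("shadow units expose the recurrent-input correlation and need p_r > 0", {
  set.seed(48)
  cfg <- lattice_config(L = 20, variant = "spatial", p_s = 0.85, bp = 0.95,
                        p_ext = 1e-3, steps = 1e4)
  run <- simulate_lattice(cfg, n_shadow = 50)
  sh <- shadow_autocorrelation(run, 30)
  expect_equal(sh$values[1], 1)
  expect_true(all(sh$values[-1] < 0.5))              # refresh noise floor
  cfg0 <- lattice_config(L = 10, variant = "spatial", p_s = 0.85, p_r = 0,
                         p_ext = 1e-3, steps = 500)
  run0 <- simulate_lattice(cfg0, n_shadow = 10)
  expect_error(shadow_autocorrelation(run0), "silent")
  expect_error(shadow_autocorrelation(simulate_lattice(cfg0)), "no shadow")
})

test_that("pair cross-correlations use Chebyshev shells with periodic wrap", {
  set.seed(49)
  cfg <- lattice_config(L = 12, variant = "spatial", p_s = 0.8, bp = 0.95,
                        p_ext = 1e-2, steps = 3000)
  run <- simulate_lattice(cfg, record = "all")
  cc <- cc_by_distance(run, distances = 1:2, n_pairs = 100, max_lag_ms = 3)
  # d = 1 shell: 4 pairs per unit (8 neighbors, each pair counted once)
  expect_equal(cc$zero_lag$distance, 1:2)
  expect_true(all(cc$zero_lag$n_pairs == 100))
  full <- cc_by_distance(run, distances = 1, n_pairs = 1e6, max_lag_ms = 1)
  expect_equal(full$zero_lag$n_pairs, 144 * 8 / 2)   # every Moore pair once
})

test_that("the fitted slow timescale grows towards criticality", {
  set.seed(50)
  taus <- sapply(c(0.95, 0.97, 0.99), function(bp) {
    cfg <- lattice_config(L = 40, variant = "spatial", p_s = 0.88, bp = bp,
                          p_ext = 1e-4, steps = 3e4)
    fit_double_exponential(unit_autocorrelation(simulate_lattice(cfg), 120),
                           t_m_ms = 100)$tau2
  })
  expect_true(all(diff(taus) > 0))
})
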