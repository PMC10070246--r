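#!/usr/bin/env Rscript
# Compare the three candidate mechanisms for multiple timescales in local
# population activity: two cell types, synaptic filtering, and spatial
# network interactions. All three produce two-timescale unit
# autocorrelations; only the spatial network makes cross-correlations decay
# with lattice distance.

library(multitau)
set.seed(1003)
dir.create("results", showWarnings = FALSE)

mechs <- list(
  two_type = lattice_config(L = 50, variant = "two_type",
                            p_s = c(0.88, 0.976), bp = 0.99, p_ext = 1e-4,
                            steps = 6e4),
  synaptic = lattice_config(L = 50, variant = "synaptic", p_s = 0.88,
                            bp = 0.99, p_ext = 1e-4, tau_synapse = 41,
                            steps = 6e4),
  spatial = lattice_config(L = 50, variant = "spatial", p_s = 0.88,
                           bp = 0.99, p_ext = 1e-4, steps = 6e4))

fits <- list(); cc_tab <- data.frame(); ac_tab <- data.frame()
for (m in names(mechs)) {
  run <- simulate_lattice(mechs[[m]], record = "all")
  ac <- unit_autocorrelation(run, 150)
  f <- fit_double_exponential(ac, t_m_ms = 100)
  fits[[m]] <- data.frame(mechanism = m, tau1 = f$tau1, tau2 = f$tau2,
                          c1 = f$c1, degenerate = f$degenerate)
  message(sprintf("%-9s unit AC: tau1 = %5.2f ms, tau2 = %6.1f ms (c1 = %.2f)",
                  m, f$tau1, f$tau2, f$c1))
  cc <- cc_by_distance(run, distances = 1:5, n_pairs = 4e3, max_lag_ms = 2)
  cc_tab <- rbind(cc_tab, cbind(mechanism = m, cc$zero_lag))
  ac_tab <- rbind(ac_tab, cbind(mechanism = m, as.data.frame(ac)))
}
message("zero-lag cross-correlation by Chebyshev distance:")
print(reshape(cc_tab[, 1:3], idvar = "mechanism", timevar = "distance",
              direction = "wide"), row.names = FALSE)
message("interpretation: random-connectivity mechanisms (two_type, synaptic)")
message("are flat in distance; the spatial network decays with distance.")

write.csv(do.call(rbind, fits), "results/03_unit_ac_fits.csv",
          row.names = FALSE)
write.csv(cc_tab, "results/03_cc_by_distance.csv", row.names = FALSE)
write.csv(ac_tab, "results/03_unit_ac_curves.csv", row.names = FALSE)
message("wrote results/03_*.csv")
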