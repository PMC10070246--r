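# multitau

Tools for detecting, estimating and mechanistically explaining **multiple
intrinsic timescales** in columnar spiking activity. The package is aimed at
systems neuroscientists analyzing laminar-array (multi-channel) recordings of
ongoing or stimulus-driven population activity, and at modelers asking which
circuit mechanisms can produce — and modulate — the timescales those
recordings show.

## What it computes

Ongoing cortical activity decorrelates on several timescales at once. The
package covers the complete chain from spikes to mechanism:

1. **Bias-aware correlation estimation.** Spikes are pooled and counted in
   2 ms bins, task-locked means are removed per condition, and the windowed
   autocorrelation is computed per window of length *N* bins as

   AC(*t<sub>j</sub>*) = Σ<sub>i≤N−j</sub> (A<sub>i</sub> − μ̂₁(j))(A<sub>i+j</sub> − μ̂₂(j)) / (σ̂² (N−j)),

   with lag-dependent means μ̂₁, μ̂₂ and an (N−1)-normalized variance σ̂².
   This estimator is biased for finite windows — the reason direct
   exponential fits underestimate slow timescales.

2. **Generative-model fitting (adaptive ABC).** The spike counts are modeled
   as a doubly stochastic process: a latent rate
   A<sub>OU</sub>(t) = Σ<sub>k</sub> √c<sub>k</sub> A<sub>τk</sub>(t)
   (a mixture of Ornstein–Uhlenbeck processes, Σc<sub>k</sub> = 1) driving
   gamma-distributed counts with dispersion α = variance/mean. Candidate
   parameters are accepted when the autocorrelation of a *matched* synthetic
   dataset (same windows, bins, count mean and variance — hence the same
   estimation bias) falls within a shrinking error threshold of the data's.
   The result is a posterior ensemble with MAP estimates and credible
   intervals; one- vs two-timescale descriptions are compared through the
   acceptance-rate approximation of the Bayes factor,
   BF(ε) = CDF<sub>M2</sub>(ε)/CDF<sub>M1</sub>(ε).

3. **Network mechanisms.** Binary-unit probabilistic networks on a periodic
   lattice (each unit driven by self-excitation p<sub>s</sub>, recurrent
   excitation p<sub>r</sub> per active neighbor, and external drive
   p<sub>ext</sub>; branching parameter BP = p<sub>s</sub> + 8p<sub>r</sub>),
   in spatial, dispersed, random, two-cell-type and synaptic-filtering
   variants, plus the closed-form timescale theory of the master equation:
   τ<sub>self</sub> = −Δt/ln p<sub>s</sub>, mode-resolved interaction
   timescales τ<sub>int,k</sub>, and the connectivity-independent global
   timescale τ<sub>global</sub> = −Δt(1−p<sub>s</sub>)/((1−BP′) ln p<sub>s</sub>)
   with BP′ = p<sub>s</sub> + 8p<sub>r</sub>.

4. **Matching and attention scenarios.** A theory-guided grid search locates
   (p<sub>s</sub>, p<sub>r</sub>) whose simulated, double-exponential-fitted
   timescales fall inside empirically observed bands, and quantifies how a
   change in lateral coupling alone reproduces the ~20% attentional increase
   of the slow timescale.

5. **Synthetic sessions.** `make_session()` builds 16-channel sessions with
   drifting receptive fields and known ground truth, so the whole pipeline
   is testable without any recorded data.

## Worked example

A spatially connected network close to criticality shows a two-timescale
unit autocorrelation: the fast component tracks the self-excitation
timescale, the slow component is an effective mixture of interaction
timescales far below the global mode.

```r
library(multitau)
set.seed(1)

cfg <- lattice_config(L = 50, variant = "spatial", p_s = 0.88, bp = 0.99,
                      p_ext = 1e-4, steps = 5e4)
run <- simulate_lattice(cfg)
run
#> <lattice_run> spatial/linear, L=50, 50000 steps, mean activity 0.009836

ac <- unit_autocorrelation(run, max_lag_ms = 150)
fit <- fit_double_exponential(ac, t_m_ms = 100)
fit
#> <double_exp_fit> tau1=7.56 ms, tau2=39.5 ms, c1=0.695 (RSS 0.000193)

c(tau_self = tau_self(0.88), tau_global = tau_global(0.88, (0.99 - 0.88) / 8))
#>   tau_self tau_global
#>   7.822683  93.872201
```

The simulated mean activity (0.0098) matches the analytic steady state
p<sub>ext</sub>/(1−BP) = 0.01. The fitted fast timescale (7.6 ms) matches
τ<sub>self</sub> = 7.8 ms; the fitted slow timescale (39.5 ms) is the
weighted average of many interaction modes and sits well below
τ<sub>global</sub> = 93.9 ms — reaching slow timescales of ~120 ms at this
p<sub>s</sub> requires moving BP to within ~10⁻³ of the critical point.

The numbered scripts under `analysis/` walk through the full workflow on
synthetic data — session generation and correlation structure (`01`), ABC
fitting and model selection (`02`), the three network mechanisms and their
cross-correlation signatures (`03`), theory-vs-simulation checks (`04`), and
the attention-matching grid search (`05`) — each writing tidy tables under
`results/`.

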