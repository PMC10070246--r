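Package: multitau
Title: Multiple Intrinsic Timescales in Columnar Spiking Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and explains multiple intrinsic timescales in columnar
    spiking activity. Provides bias-aware auto- and cross-correlation
    estimators for binned spike counts, a doubly stochastic generative model
    (mixtures of Ornstein-Uhlenbeck processes driving gamma-dispersed counts)
    fitted by adaptive Approximate Bayesian Computation with Bayes-factor
    model selection, fast binary-unit lattice network simulators (spatial,
    dispersed, random, two-cell-type and synaptic-filtering variants with
    linear or nonlinear interaction rules), closed-form timescale predictions
    from the corresponding master-equation analysis, and a parameter-matching
    procedure that links network excitability to attentional modulation of
    the slow timescale. Includes a synthetic-session generator emulating
    16-channel columnar recordings with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    Rcpp,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
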