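#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Compiled hot path for the ABC loop: simulate one matched dataset from the
// OU-mixture generative model and return its window-averaged windowed
// autocorrelation. Mirrors simulate_ou_mixture() + sample_counts() +
// windowed_ac_matrix() in R (which remain the tested reference path).

namespace {

// ziggurat tables for the standard normal (Marsaglia & Tsang layout)
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;
static void zig_init() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1); zig_kn[1] = 0;
  zig_wn[0] = q / m1; zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0; zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; --i) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1); tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn); zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    if (!zig_ready) zig_init();
    uint64_t z = seed;
    auto next = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      return x ^ (x >> 31);
    };
    s0 = next(); s1 = next();
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next_u64() {
    uint64_t x = s0; const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double runif() {
    double u = (next_u64() >> 11) * (1.0 / 9007199254740992.0);
    return (u > 0.0) ? u : 5e-324;
  }
  inline double rnorm() {            // ziggurat
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next_u64() & 0xffffffffULL);
      uint32_t iz = (uint32_t)(hz & 127);
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < zig_kn[iz]) return hz * zig_wn[iz];
      if (iz == 0) {                 // tail
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(runif()) / r;
          y = -std::log(runif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      double x = hz * zig_wn[iz];
      if (zig_fn[iz] + runif() * (zig_fn[iz - 1] - zig_fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
  // Marsaglia-Tsang; shape < 1 boosted via Gamma(a+1) U^(1/a)
  double rgamma(double shape, double scale) {
    if (shape <= 0.0) return 0.0;
    double boost = 1.0;
    if (shape < 1.0) {
      boost = std::pow(runif(), 1.0 / shape);
      shape += 1.0;
    }
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = rnorm(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = runif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v * boost * scale;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
        return d * v * boost * scale;
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector cpp_matched_ac(NumericVector tau, NumericVector ck,
                             double alpha, int n_trials, int n_bins,
                             double bin_ms, double count_mean,
                             double count_var, int max_lag) {
  const int K = tau.size();
  NumericVector out(max_lag + 1, NA_REAL);
  double rate_var = count_var - alpha * count_mean;
  if (rate_var < 0.0 || alpha <= 0.0) return out;   // infeasible candidate
  const double rate_sd = std::sqrt(rate_var);

  uint64_t seed;
  {
    RNGScope scope;
    seed = (uint64_t)(unif_rand() * 4294967296.0) * 4294967296ULL +
           (uint64_t)(unif_rand() * 4294967296.0);
  }
  Rng rng(seed);

  std::vector<double> phi(K), isd(K), amp(K);
  for (int k = 0; k < K; ++k) {
    phi[k] = std::exp(-bin_ms / tau[k]);
    isd[k] = std::sqrt(1.0 - phi[k] * phi[k]);
    amp[k] = std::sqrt(ck[k]);
  }

  std::vector<double> x(n_bins), state(K), acc(max_lag + 1, 0.0);
  int used = 0;
  for (int tr = 0; tr < n_trials; ++tr) {
    // latent mixture (stationary AR(1) components, unit variance each)
    for (int i = 0; i < n_bins; ++i) x[i] = 0.0;
    for (int k = 0; k < K; ++k) {
      if (ck[k] == 0.0) continue;
      double s = rng.rnorm();
      x[0] += amp[k] * s;
      for (int i = 1; i < n_bins; ++i) {
        s = phi[k] * s + isd[k] * rng.rnorm();
        x[i] += amp[k] * s;
      }
    }
    // gamma-dispersed counts with matched moments (rates clipped at 0)
    double S1 = 0.0, S2 = 0.0;
    for (int i = 0; i < n_bins; ++i) {
      double lam = count_mean + rate_sd * x[i];
      double c = (lam > 0.0) ? rng.rgamma(lam / alpha, alpha) : 0.0;
      x[i] = c; S1 += c; S2 += c * c;
    }
    // windowed AC with lag-dependent means, (N-1)-normalized variance
    const double N = n_bins;
    double sigma2 = (S2 - S1 * S1 / N) / (N - 1.0);
    if (sigma2 <= 0.0) continue;
    ++used;
    std::vector<double> pref(n_bins + 1, 0.0);    // prefix sums for means
    for (int i = 0; i < n_bins; ++i) pref[i + 1] = pref[i] + x[i];
    for (int j = 0; j <= max_lag; ++j) {
      int n = n_bins - j;
      double pr = 0.0;
      for (int i = 0; i < n; ++i) pr += x[i] * x[i + j];
      double m1 = pref[n] / n;
      double m2 = (pref[n_bins] - pref[j]) / n;
      acc[j] += (pr - n * m1 * m2) / (sigma2 * n);
    }
  }
  if (used == 0) return out;
  for (int j = 0; j <= max_lag; ++j) out[j] = acc[j] / used;
  return out;
}
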