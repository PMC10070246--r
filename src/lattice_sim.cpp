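#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast deterministic RNG (xorshift128+), seeded from R's RNG so that
// set.seed() fully controls simulation runs while keeping the per-draw
// cost negligible next to R's generator.
struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128(uint64_t seed) {
    // splitmix64 expansion of the seed
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
  inline uint64_t next() {
    uint64_t x = s0; const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Synchronous update of a binary-unit network (in-edge list connectivity).
// rule: 0 = linear (additive), 1 = nonlinear (multiplicative),
//       2 = synaptic filtering (linear on low-pass filtered recurrent input)
// Shadow units: unit s (s < n_shadow) gets a passive companion driven only
// by the recurrent input of unit s; it never feeds back into the network.
// [[Rcpp::export]]
List cpp_lattice_simulate(NumericVector ps, NumericVector pr, double p_ext,
                          IntegerMatrix adj, int rule, double tau_syn,
                          int steps, int burnin, IntegerVector init,
                          IntegerVector record_idx, int n_shadow) {
  const int n = ps.size();
  const int k = adj.ncol();
  const int n_rec = record_idx.size();
  if (adj.nrow() != n) stop("adjacency must have one row per unit");

  std::vector<unsigned char> S(n), Snew(n);
  for (int i = 0; i < n; ++i) S[i] = (unsigned char)(init[i] != 0);

  std::vector<double> f;               // synaptic filter state
  if (rule == 2) f.assign(n, 0.0);
  std::vector<unsigned char> shadow(std::max(n_shadow, 0), 0);

  RawMatrix rec(n_rec, steps);
  RawMatrix shadow_rec(n_shadow, steps);
  NumericVector pooled(steps);
  double clip_count = 0.0, act_sum = 0.0;

  uint64_t seed;
  {
    RNGScope scope;                    // derive the stream from R's RNG
    seed = (uint64_t)(unif_rand() * 4294967296.0) * 4294967296ULL +
           (uint64_t)(unif_rand() * 4294967296.0);
  }
  XorShift128 rng(seed);
  const double inv_tau = (rule == 2) ? 1.0 / tau_syn : 0.0;

  for (int t = -burnin; t < steps; ++t) {
    for (int i = 0; i < n; ++i) {
      int nact = 0;
      for (int j = 0; j < k; ++j) nact += S[adj(i, j)];
      double p, drive;
      if (rule == 1) {                  // multiplicative
        double q = std::pow(1.0 - pr[i], (double)nact);
        if (S[i]) p = 1.0 - (1.0 - p_ext) * (1.0 - ps[i]) * q;
        else      p = 1.0 - (1.0 - p_ext) * q;
        drive = 1.0 - q;
      } else {
        if (rule == 2) {
          f[i] += (pr[i] * nact - f[i]) * inv_tau;
          drive = f[i];
        } else {
          drive = pr[i] * nact;
        }
        p = p_ext + drive + (S[i] ? ps[i] : 0.0);
        if (p > 1.0) { p = 1.0; clip_count += 1.0; }
        else if (p < 0.0) { p = 0.0; clip_count += 1.0; }
      }
      Snew[i] = (rng.runif() < p) ? 1 : 0;
      if (i < n_shadow) {
        double pd = drive;
        if (pd > 1.0) pd = 1.0; else if (pd < 0.0) pd = 0.0;
        shadow[i] = (rng.runif() < pd) ? 1 : 0;
      }
    }
    std::swap(S, Snew);
    if (t >= 0) {
      int tot = 0;
      for (int i = 0; i < n; ++i) tot += S[i];
      pooled[t] = tot;
      act_sum += (double)tot / n;
      for (int r = 0; r < n_rec; ++r) rec(r, t) = S[record_idx[r]];
      for (int s = 0; s < n_shadow; ++s) shadow_rec(s, t) = shadow[s];
    }
  }

  return List::create(_["record"] = rec, _["shadow"] = shadow_rec,
                      _["pooled"] = pooled,
                      _["mean_activity"] = act_sum / steps,
                      _["clip_count"] = clip_count);
}

// sparse (event-time) representation of one raw history row
static void row_events(const RawMatrix& rec, int i,
                       std::vector<int>& times, std::vector<double>& vals,
                       double& sum, double& sumsq) {
  const int T = rec.ncol();
  times.clear(); vals.clear(); sum = 0.0; sumsq = 0.0;
  for (int t = 0; t < T; ++t) {
    double v = rec(i, t);
    if (v != 0.0) {
      times.push_back(t); vals.push_back(v);
      sum += v; sumsq += v * v;
    }
  }
}

// lag-l product sums P_l = sum_t x_t x_{t+l} for l = 0..max_lag from the
// sparse representation (two-pointer over event times)
static void lag_products(const std::vector<int>& ta,
                         const std::vector<double>& va,
                         const std::vector<int>& tb,
                         const std::vector<double>& vb,
                         int max_lag, std::vector<double>& P) {
  P.assign(max_lag + 1, 0.0);
  const size_t na = ta.size(), nb = tb.size();
  size_t lo = 0;
  for (size_t i = 0; i < na; ++i) {
    while (lo < nb && tb[lo] < ta[i]) ++lo;
    for (size_t j = lo; j < nb; ++j) {
      int l = tb[j] - ta[i];
      if (l > max_lag) break;
      P[l] += va[i] * vb[j];
    }
  }
}

// prefix count of events with time < t
static double head_sum(const std::vector<int>& times,
                       const std::vector<double>& vals, int t) {
  size_t lo = std::lower_bound(times.begin(), times.end(), t) -
              times.begin();
  double s = 0.0;
  for (size_t i = 0; i < lo; ++i) s += vals[i];
  return s;
}

// Average long-run autocorrelation across rows of a raw history matrix.
// Per row: full-series mean and variance; lag-l covariance normalized by
// (T - l); rows with zero variance are skipped.
// [[Rcpp::export]]
List cpp_unit_ac(RawMatrix rec, int max_lag) {
  const int n = rec.nrow(), T = rec.ncol();
  if (max_lag >= T) stop("max_lag must be smaller than the series length");
  NumericVector ac(max_lag + 1);
  int used = 0;
  std::vector<int> times; std::vector<double> vals, P;
  std::vector<double> headv, tailv;
  for (int i = 0; i < n; ++i) {
    double sum, sumsq;
    row_events(rec, i, times, vals, sum, sumsq);
    double mu = sum / T;
    double v = sumsq / T - mu * mu;
    if (v <= 0.0) continue;
    ++used;
    lag_products(times, vals, times, vals, max_lag, P);
    // cumulative event sums from both ends for the edge corrections
    const size_t ne = times.size();
    headv.assign(max_lag + 1, 0.0);   // sum of x_t for t in [0, T-l)
    tailv.assign(max_lag + 1, 0.0);   // sum of x_t for t in [l, T)
    for (int l = 0; l <= max_lag; ++l) {
      headv[l] = sum; tailv[l] = sum;
    }
    // subtract events falling outside the overlap region
    for (size_t e = 0; e < ne; ++e) {
      int t_from_end = T - 1 - times[e];     // 0-based distance to the end
      if (t_from_end <= max_lag)
        for (int l = t_from_end + 1; l <= max_lag; ++l) headv[l] -= vals[e];
      if (times[e] <= max_lag)
        for (int l = times[e] + 1; l <= max_lag; ++l) tailv[l] -= vals[e];
    }
    for (int l = 0; l <= max_lag; ++l) {
      double cov = P[l] - mu * (headv[l] + tailv[l]) + (T - l) * mu * mu;
      ac[l] += cov / ((T - l) * v);
    }
  }
  if (used > 0) for (int l = 0; l <= max_lag; ++l) ac[l] /= used;
  return List::create(_["ac"] = ac, _["n_units"] = used);
}

// Same estimator for one numeric series (e.g. pooled network activity).
// [[Rcpp::export]]
NumericVector cpp_series_ac(NumericVector xin, int max_lag) {
  const int T = xin.size();
  if (max_lag >= T) stop("max_lag must be smaller than the series length");
  std::vector<double> x(T);
  double s = 0.0;
  for (int t = 0; t < T; ++t) s += xin[t];
  double mu = s / T, v = 0.0;
  for (int t = 0; t < T; ++t) { x[t] = xin[t] - mu; v += x[t] * x[t]; }
  v /= T;
  if (v <= 0.0) stop("series has zero variance");
  NumericVector ac(max_lag + 1);
  for (int l = 0; l <= max_lag; ++l) {
    double c = 0.0;
    for (int t = 0; t + l < T; ++t) c += x[t] * x[t + l];
    ac[l] = c / ((T - l) * v);
  }
  return ac;
}

// Mean cross-correlation over row pairs (a leading b), plus per-pair
// zero-lag values. Pairs with a constant row are skipped.
// [[Rcpp::export]]
List cpp_pair_cc(RawMatrix rec, IntegerVector ia, IntegerVector ib,
                 int max_lag) {
  const int T = rec.ncol(), np = ia.size();
  if (max_lag >= T) stop("max_lag must be smaller than the series length");
  NumericVector mean_cc(max_lag + 1), lag0(np, NA_REAL);
  int used = 0;
  std::vector<int> tta, ttb; std::vector<double> vva, vvb, P;
  for (int p = 0; p < np; ++p) {
    double sa, sb, qa, qb;
    row_events(rec, ia[p], tta, vva, sa, qa);
    row_events(rec, ib[p], ttb, vvb, sb, qb);
    double ma = sa / T, mb = sb / T;
    double va = qa / T - ma * ma, vb = qb / T - mb * mb;
    if (va <= 0.0 || vb <= 0.0) continue;
    ++used;
    lag_products(tta, vva, ttb, vvb, max_lag, P);
    double norm = std::sqrt(va * vb);
    for (int l = 0; l <= max_lag; ++l) {
      double head = head_sum(tta, vva, T - l);  // sum a_t, t < T - l
      double tail = sb - head_sum(ttb, vvb, l); // sum b_t, t >= l
      double cov = P[l] - mb * head - ma * tail + (T - l) * ma * mb;
      double c = cov / ((T - l) * norm);
      mean_cc[l] += c;
      if (l == 0) lag0[p] = c;
    }
  }
  if (used > 0) for (int l = 0; l <= max_lag; ++l) mean_cc[l] /= used;
  return List::create(_["mean_cc"] = mean_cc, _["lag0"] = lag0,
                      _["n_pairs"] = used);
}
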