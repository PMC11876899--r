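// Core Euler-walk simulator for the relative-start-time drift diffusion
// model, plus the simulation-based likelihood evaluated over choice x RT-bin
// histograms.  All randomness is driven by a platform-independent
// xoshiro256++ generator seeded through splitmix64, so identical seeds give
// bit-identical paths on any build of this file.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 (seeding) + xoshiro256++ (stream) + Marsaglia polar normals
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1); never exactly 0 so log() below is safe
  inline double runif01() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double rnorm01() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif01() - 1.0;
      v = 2.0 * runif01() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Latency gates: entry step of each attribute given RST (seconds) and dt.
// RST >= 0: self-payoff difference enters at step 0, other-payoff at
// ceil(|RST|/dt); RST < 0 the mirror image.
// ---------------------------------------------------------------------------

static inline void entry_steps(double rst, double dt, int &entry_s, int &entry_o) {
  if (rst >= 0.0) {
    entry_s = 0;
    entry_o = (int)std::ceil(rst / dt - 1e-12);
  } else {
    entry_o = 0;
    entry_s = (int)std::ceil(-rst / dt - 1e-12);
  }
}

// One path.  Returns +1 (upper boundary, larger-Ms option), 0 (lower), or
// -1 (censored at t_max).  rt excludes censored paths' ndt convention: for
// absorbed paths rt = n_steps * dt + ndt; for censored paths rt = NA upstream.
struct PathResult { int choice; int n_steps; };

// The gates define two phases of constant drift: before the late
// attribute's entry step only the early attribute contributes, afterwards
// both do.  Splitting the walk keeps the inner loop branch-free.
template <class NoiseFn>
static inline PathResult run_path(double drift_s, double drift_o,
                                  int entry_s, int entry_o,
                                  double threshold, double bias,
                                  double dt, int max_steps,
                                  NoiseFn &&noise) {
  const int entry_late = (entry_s > entry_o) ? entry_s : entry_o;
  const double early = (entry_s == 0 ? drift_s : 0.0) +
                       (entry_o == 0 ? drift_o : 0.0);
  const double full = drift_s + drift_o;
  double E = bias;
  const int phase1 = (entry_late < max_steps) ? entry_late : max_steps;
  const double d1 = early * dt;
  for (int k = 0; k < phase1; ++k) {
    E += d1 + noise(k);
    if (E >= threshold)  return PathResult{1, k + 1};
    if (E <= -threshold) return PathResult{0, k + 1};
  }
  const double d2 = full * dt;
  for (int k = phase1; k < max_steps; ++k) {
    E += d2 + noise(k);
    if (E >= threshold)  return PathResult{1, k + 1};
    if (E <= -threshold) return PathResult{0, k + 1};
  }
  return PathResult{-1, max_steps};
}

// ---------------------------------------------------------------------------
// Free simulation (fresh RNG stream per call)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_paths(int n, double dms, double dmo,
                        double omega_s, double omega_o, double rst,
                        double threshold, double ndt, double bias,
                        double sigma, double dt, double t_max,
                        double seed) {
  if (!R_finite(dms) || !R_finite(dmo) || !R_finite(omega_s) ||
      !R_finite(omega_o) || !R_finite(rst) || !R_finite(threshold) ||
      !R_finite(ndt) || !R_finite(bias) || !R_finite(sigma) || !R_finite(dt))
    stop("non-finite parameter passed to simulator");
  int entry_s, entry_o;
  entry_steps(rst, dt, entry_s, entry_o);
  const int max_steps = (int)std::ceil(t_max / dt - 1e-12);
  const double ds = omega_s * dms, dv = omega_o * dmo;
  Xoshiro rng((uint64_t)(int64_t)seed);
  IntegerVector choice(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    PathResult pr = run_path(ds, dv, entry_s, entry_o, threshold, bias, dt,
                             max_steps,
                             [&](int) { return sigma * rng.rnorm01(); });
    choice[i] = pr.choice;
    rt[i] = (pr.choice < 0) ? NA_REAL : pr.n_steps * dt + ndt;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

// Single path with the full evidence trajectory (diagnostics / plotting).
// [[Rcpp::export]]
List cpp_simulate_path_trace(double dms, double dmo,
                             double omega_s, double omega_o, double rst,
                             double threshold, double ndt, double bias,
                             double sigma, double dt, double t_max,
                             double seed) {
  int entry_s, entry_o;
  entry_steps(rst, dt, entry_s, entry_o);
  const int max_steps = (int)std::ceil(t_max / dt - 1e-12);
  const double ds = omega_s * dms, dv = omega_o * dmo;
  Xoshiro rng((uint64_t)(int64_t)seed);
  std::vector<double> evidence, drift;
  evidence.reserve(256); drift.reserve(256);
  evidence.push_back(bias);
  double E = bias;
  int choice = -1, n_steps = max_steps;
  for (int k = 0; k < max_steps; ++k) {
    double nu = 0.0;
    if (k >= entry_s) nu += ds;
    if (k >= entry_o) nu += dv;
    E += nu * dt + sigma * rng.rnorm01();
    evidence.push_back(E);
    drift.push_back(nu);
    if (std::fabs(E) >= threshold) {
      choice = (E > 0) ? 1 : 0;
      n_steps = k + 1;
      break;
    }
  }
  return List::create(
    _["choice"] = choice,
    _["rt"] = (choice < 0) ? NA_REAL : n_steps * dt + ndt,
    _["evidence"] = NumericVector(evidence.begin(), evidence.end()),
    _["drift"] = NumericVector(drift.begin(), drift.end()),
    _["n_steps"] = n_steps);
}

// ---------------------------------------------------------------------------
// Pooled noise for the simulation-based likelihood (common random numbers)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_make_noise_pool(int size, double seed) {
  if (size <= 0 || (size & (size - 1)) != 0)
    stop("noise pool size must be a positive power of two");
  Xoshiro rng((uint64_t)(int64_t)seed ^ 0xA5A5A5A5A5A5A5A5ULL);
  NumericVector pool(size);
  for (int i = 0; i < size; ++i) pool[i] = rng.rnorm01();
  return pool;
}

static inline uint64_t offset_hash(uint64_t seed, uint64_t trial,
                                   uint64_t sim, uint64_t salt) {
  uint64_t x = seed ^ (trial * 0x9E3779B97F4A7C15ULL) ^
               (sim * 0xBF58476D1CE4E5B9ULL) ^ (salt * 0xD6E8FEB86659FD93ULL);
  return splitmix64(x);
}

// Simulate the n_sims outcomes the likelihood uses for one trial, reading
// noise from the shared pool at a per-(trial, sim) deterministic offset.
static void sim_trial_pooled(double dms, double dmo,
                             double omega_s, double omega_o, double rst,
                             double threshold, double bias,
                             double sigma, double dt, int max_steps,
                             int n_sims, const double *pool, int pool_size,
                             uint64_t seed, uint64_t trial_idx, uint64_t salt,
                             int *choice_out, int *steps_out) {
  int entry_s, entry_o;
  entry_steps(rst, dt, entry_s, entry_o);
  const double ds = omega_s * dms, dv = omega_o * dmo;
  const uint64_t mask = (uint64_t)pool_size - 1;
  for (int j = 0; j < n_sims; ++j) {
    const uint64_t off = offset_hash(seed, trial_idx, (uint64_t)j, salt);
    PathResult pr = run_path(
        ds, dv, entry_s, entry_o, threshold, bias, dt, max_steps,
        [&](int k) { return sigma * pool[(off + (uint64_t)k) & mask]; });
    choice_out[j] = pr.choice;
    steps_out[j] = pr.n_steps;
  }
}

// Exported so R can reproduce, outcome by outcome, exactly the simulated set
// the likelihood below bins for a given trial (dual-route testing).
// [[Rcpp::export]]
List cpp_sim_trial_pooled(double dms, double dmo,
                          double omega_s, double omega_o, double rst,
                          double threshold, double ndt, double bias,
                          double sigma, double dt, double t_max,
                          int n_sims, NumericVector pool,
                          double seed, int trial_idx, double salt) {
  const int max_steps = (int)std::ceil(t_max / dt - 1e-12);
  std::vector<int> ch(n_sims), st(n_sims);
  sim_trial_pooled(dms, dmo, omega_s, omega_o, rst, threshold, bias, sigma,
                   dt, max_steps, n_sims, REAL(pool), pool.size(),
                   (uint64_t)(int64_t)seed, (uint64_t)trial_idx,
                   (uint64_t)(int64_t)salt, ch.data(), st.data());
  IntegerVector choice(n_sims);
  NumericVector rt(n_sims);
  for (int j = 0; j < n_sims; ++j) {
    choice[j] = ch[j];
    rt[j] = (ch[j] < 0) ? NA_REAL : st[j] * dt + ndt;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

// ---------------------------------------------------------------------------
// Negative log-likelihood over a subject's trials.
//
// Cells: choice 0 x n_bins RT bins, choice 1 x n_bins, plus one censored
// cell; Laplace smoothing with `pseudo` mass per cell.  RT bins cover
// [ndt, ndt + t_max] in steps of bin_width; observed RTs outside clamp to
// the nearest boundary bin.  Status vectors are 0 = better, 1 = equal,
// 2 = worse; omega_s3 / omega_o3 / rst3 are the status-resolved parameter
// triples (variants collapse shared slots upstream).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_negloglik(NumericVector dms, NumericVector dmo,
                     IntegerVector status,
                     IntegerVector obs_choice, NumericVector obs_rt,
                     NumericVector omega_s3, NumericVector omega_o3,
                     NumericVector rst3,
                     double threshold, double ndt, double bias,
                     double sigma, double dt, double t_max,
                     int n_sims, double bin_width, double pseudo,
                     NumericVector pool, double seed, double salt) {
  const int n_trials = dms.size();
  if (n_trials == 0) stop("no trials supplied to likelihood");
  for (int i = 0; i < 3; ++i)
    if (!R_finite(omega_s3[i]) || !R_finite(omega_o3[i]) || !R_finite(rst3[i]))
      stop("non-finite parameter passed to likelihood");
  if (!R_finite(threshold) || !R_finite(ndt) || !R_finite(bias))
    stop("non-finite parameter passed to likelihood");
  const int max_steps = (int)std::ceil(t_max / dt - 1e-12);
  const int n_bins = (int)std::ceil(t_max / bin_width - 1e-12);
  const int n_cells = 2 * n_bins + 1;
  std::vector<int> ch(n_sims), st(n_sims);
  std::vector<int> counts(n_cells);
  double nll = 0.0;
  for (int i = 0; i < n_trials; ++i) {
    const int s = status[i];
    sim_trial_pooled(dms[i], dmo[i], omega_s3[s], omega_o3[s], rst3[s],
                     threshold, bias, sigma, dt, max_steps, n_sims,
                     REAL(pool), pool.size(), (uint64_t)(int64_t)seed,
                     (uint64_t)i, (uint64_t)(int64_t)salt,
                     ch.data(), st.data());
    std::fill(counts.begin(), counts.end(), 0);
    for (int j = 0; j < n_sims; ++j) {
      if (ch[j] < 0) { counts[n_cells - 1]++; continue; }
      // bin on (rt - ndt) exactly as the R reference route does, so the
      // two implementations agree bit-for-bit at bin boundaries
      const double rel = (st[j] * dt + ndt) - ndt;
      int b = (rel <= 0.0) ? 0 : (int)(rel / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      counts[ch[j] * n_bins + b]++;
    }
    // observed cell; an RT below the model's minimum possible response
    // (ndt + dt) is impossible under these parameters and receives only
    // the smoothing floor -- clamping it into the first bin's real mass
    // would let arbitrarily large ndt values soak up all observations
    const double denom = n_sims + pseudo * n_cells;
    double p;
    if (obs_choice[i] < 0 || !R_finite(obs_rt[i])) {
      p = (counts[n_cells - 1] + pseudo) / denom;  // censored / missing
    } else {
      double rel = obs_rt[i] - ndt;
      if (rel < dt) {
        p = pseudo / denom;
      } else {
        int b = (int)(rel / bin_width);
        if (b >= n_bins) b = n_bins - 1;
        p = (counts[obs_choice[i] * n_bins + b] + pseudo) / denom;
      }
    }
    nll -= std::log(p);
  }
  if (!R_finite(nll)) stop("non-finite negative log-likelihood");
  return nll;
}
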