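#include <Rcpp.h>
using namespace Rcpp;

// Elementary step of the multi-clone process: one competitive cell is removed
// (clone k with probability n_k/N) and one is added from a compensation source
// drawn with probability (lambda*n_k + eps)/(lambda*N + eps*K), both weights
// evaluated on the pre-removal state. Uses R's RNG throughout so set.seed()
// in R makes every run reproducible.

static inline int sample_loss(const std::vector<int> &counts, int N) {
  double u = unif_rand() * N;
  double acc = 0.0;
  int K = (int) counts.size();
  for (int k = 0; k < K; ++k) {
    acc += counts[k];
    if (u < acc) return k;
  }
  return K - 1;  // guard against rounding
}

static inline int sample_comp(const std::vector<int> &counts, double eps,
                              double lam, double denom) {
  int K = (int) counts.size();
  if (lam == 0.0) {  // uniform over clones
    int k = (int) (unif_rand() * K);
    return k >= K ? K - 1 : k;
  }
  double u = unif_rand() * denom;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += lam * counts[k] + eps;
    if (u < acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_multi(IntegerVector init, double eps, double lam,
                                 IntegerVector record_steps) {
  int K = init.size();
  int N = 0;
  std::vector<int> counts(K);
  for (int k = 0; k < K; ++k) { counts[k] = init[k]; N += init[k]; }
  double denom = lam * N + eps * K;

  int n_rec = record_steps.size();
  IntegerMatrix out(K, n_rec);
  int rec = 0;
  long long n_steps = n_rec > 0 ? (long long) record_steps[n_rec - 1] : 0;

  if (rec < n_rec && record_steps[rec] == 0) {
    for (int k = 0; k < K; ++k) out(k, rec) = counts[k];
    ++rec;
  }
  for (long long m = 1; m <= n_steps; ++m) {
    int loss = sample_loss(counts, N);
    int comp = sample_comp(counts, eps, lam, denom);
    if (loss != comp) { --counts[loss]; ++counts[comp]; }
    if (rec < n_rec && (long long) record_steps[rec] == m) {
      for (int k = 0; k < K; ++k) out(k, rec) = counts[k];
      ++rec;
    }
  }
  return out;
}

// Monoclonality indicator (any n_k == N) at each checkpoint, for one replicate.
// When eps == 0 a monoclonal state is absorbing, so later checkpoints are
// filled without further simulation.
// [[Rcpp::export]]
LogicalVector cpp_monoclonal_one(IntegerVector init, double eps, double lam,
                                 IntegerVector checkpoints) {
  int K = init.size();
  int N = 0;
  std::vector<int> counts(K);
  for (int k = 0; k < K; ++k) { counts[k] = init[k]; N += init[k]; }
  double denom = lam * N + eps * K;

  int n_chk = checkpoints.size();
  LogicalVector out(n_chk);
  int chk = 0;
  long long n_steps = (long long) checkpoints[n_chk - 1];

  for (long long m = 0; m <= n_steps && chk < n_chk; ++m) {
    if (m > 0) {
      int loss = sample_loss(counts, N);
      int comp = sample_comp(counts, eps, lam, denom);
      if (loss != comp) { --counts[loss]; ++counts[comp]; }
    }
    if ((long long) checkpoints[chk] == m) {
      bool mono = false;
      for (int k = 0; k < K; ++k) if (counts[k] == N) { mono = true; break; }
      out[chk++] = mono;
      if (mono && eps == 0.0) {         // absorbed: fixation is permanent
        while (chk < n_chk) out[chk++] = true;
        return out;
      }
    }
  }
  return out;
}

// Embedded single-clone birth-death chain. eps_supply is the supply weight in
// the numerator of the focal lineage (eps for a whole clone or a labeled
// master cell's sub-lineage; 0 for a labeled competitive cell's sub-lineage);
// the denominator always carries the full-model weight eps*K + lam*N.
struct BDRates {
  std::vector<double> up, dn;
  BDRates(double eps_supply, double eps, double lam, int K, int N) :
      up(N + 1), dn(N + 1) {
    double denom = lam * (double) N + eps * (double) K;
    for (int n = 0; n <= N; ++n) {
      double q = (eps_supply + lam * n) / denom;
      up[n] = q * (1.0 - (double) n / N);
      dn[n] = (1.0 - q) * ((double) n / N);
    }
  }
};

// [[Rcpp::export]]
IntegerVector cpp_birth_death(double eps_supply, double eps, double lam,
                              int K, int N, int n0,
                              IntegerVector record_steps) {
  BDRates r(eps_supply, eps, lam, K, N);
  int n_rec = record_steps.size();
  IntegerVector out(n_rec);
  int rec = 0;
  long long n_steps = (long long) record_steps[n_rec - 1];
  int n = n0;

  if (rec < n_rec && record_steps[rec] == 0) out[rec++] = n;
  for (long long m = 1; m <= n_steps; ++m) {
    double u = unif_rand();
    if (u < r.up[n]) ++n;
    else if (u < r.up[n] + r.dn[n]) --n;
    if (rec < n_rec && (long long) record_steps[rec] == m) out[rec++] = n;
  }
  return out;
}

// Full per-step series of the single-clone chain (event clock, includes
// no-change steps), for burst detection.
// [[Rcpp::export]]
IntegerVector cpp_birth_death_series(double eps_supply, double eps, double lam,
                                     int K, int N, int n0, int n_steps) {
  BDRates r(eps_supply, eps, lam, K, N);
  IntegerVector out(n_steps + 1);
  int n = n0;
  out[0] = n;
  for (int m = 1; m <= n_steps; ++m) {
    double u = unif_rand();
    if (u < r.up[n]) ++n;
    else if (u < r.up[n] + r.dn[n]) --n;
    out[m] = n;
  }
  return out;
}

// Monte-Carlo splitting/first-passage on the single-clone chain: from n0, run
// until hitting `lower` or `upper`. Returns hits of the upper boundary, and
// total step counts conditional on each outcome.
// [[Rcpp::export]]
List cpp_splitting_mc(double eps_supply, double eps, double lam, int K, int N,
                      int n0, int lower, int upper, int n_reps) {
  BDRates r(eps_supply, eps, lam, K, N);
  long long hits = 0;
  double steps_up = 0.0, steps_dn = 0.0;
  for (int rep = 0; rep < n_reps; ++rep) {
    int n = n0;
    long long m = 0;
    while (n != lower && n != upper) {
      double u = unif_rand();
      if (u < r.up[n]) ++n;
      else if (u < r.up[n] + r.dn[n]) --n;
      ++m;
    }
    if (n == upper) { ++hits; steps_up += (double) m; }
    else steps_dn += (double) m;
  }
  return List::create(
    _["hits_upper"] = (double) hits,
    _["n_reps"] = n_reps,
    _["mean_steps_upper"] = hits > 0 ? steps_up / hits : NA_REAL,
    _["mean_steps_lower"] = hits < n_reps ? steps_dn / (n_reps - hits) : NA_REAL);
}
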