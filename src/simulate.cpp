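#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time Bernoulli thinning of a log-linear self-exciting intensity.
//
// base_log[i] is the log expected count per observation bin (width obs_bin
// seconds) contributed by everything except spike history, at fine step i of
// width dt. group[i] (1-based) selects the column of `coefs` (K x G) holding
// the history log-gains in force at step i. The history covariate N_k is the
// spike count in the sliding window [t - k*hist_bin, t - (k-1)*hist_bin),
// updated online as spikes are emitted, so feedback crosses trial and
// interval boundaries over continuous session time.
//
// Emits at most one spike per fine step; errors if lambda*dt reaches 1.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericVector thinning_sim(NumericVector base_log, IntegerVector group,
                           NumericMatrix coefs, double dt, double obs_bin,
                           double hist_bin) {
  int n = base_log.size();
  int K = coefs.nrow();
  int m = (int) std::lround(hist_bin / dt);
  if (m < 1) stop("hist_bin must be >= the simulation resolution");
  if (group.size() != n) stop("group must match base_log in length");
  std::vector<int> cum(n + 1, 0);
  std::vector<int> spike(n, 0);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    cum[i] = (i > 0) ? cum[i - 1] + spike[i - 1] : 0;
    int g = group[i] - 1;
    if (g < 0 || g >= coefs.ncol()) stop("group index out of range");
    double h = 0.0;
    for (int k = 0; k < K; ++k) {
      int hi = i - k * m;
      int lo = i - (k + 1) * m;
      if (hi < 0) hi = 0;
      if (lo < 0) lo = 0;
      int N = cum[hi] - cum[lo];
      if (N) h += coefs(k, g) * N;
    }
    double p = std::exp(base_log[i] + h) / obs_bin * dt;
    if (p >= 1.0)
      stop("intensity * sim_resolution >= 1 at t = %f s; "
           "use a smaller sim_resolution or a tamer intensity",
           i * dt);
    if (unif_rand() < p) spike[i] = 1;
  }
  std::vector<double> times;
  times.reserve(256);
  for (int i = 0; i < n; ++i)
    if (spike[i]) times.push_back((i + 0.5) * dt);
  return wrap(times);
}
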