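#include <Rcpp.h>
using namespace Rcpp;

// Core Euler-Maruyama stepper for a race between k accumulator pools sharing
// feedforward inhibition.  Per step each pool i draws an increment
// E_i ~ N(drift_i * dt, sigma^2 * dt); the common inhibition is
// I = f * sum(E) / k and y_i += E_i - I.  The first pool among the first
// n_choosable whose evidence reaches `threshold` determines the outcome.
// Pools beyond n_choosable (the distractor pool in the mutual inhibition
// model) accumulate and inhibit but never trigger a decision.
//
// `cap` (optional, per-trial) limits the number of steps actually simulated;
// it is used by the dual route combiner, which only needs a route's outcome
// up to the point where the other route has already decided.
//
// Returns choice (1 = first pool, 2 = second, 0 = none), the decision step
// (0 if none) and the decided flag.  Simultaneous crossings within one step
// are broken by a uniform coin.
// [[Rcpp::export]]
List race_kernel(NumericMatrix drift, double sigma, double f,
                 double threshold, double timeout, double dt,
                 int n_choosable, Nullable<IntegerVector> cap = R_NilValue) {
  const int n = drift.nrow(), k = drift.ncol();
  const int max_steps = (int) std::ceil(timeout / dt - 1e-9);
  IntegerVector choice(n), step(n);
  LogicalVector decided(n);
  const double sddt = sigma * std::sqrt(dt);
  IntegerVector capv;
  bool has_cap = cap.isNotNull();
  if (has_cap) capv = cap.get();

  std::vector<double> y(k), E(k), mu(k);
  for (int i = 0; i < n; ++i) {
    int lim = max_steps;
    if (has_cap && capv[i] < lim) lim = capv[i];
    for (int j = 0; j < k; ++j) { y[j] = 0.0; mu[j] = drift(i, j) * dt; }
    int ch = 0, st = 0;
    for (int s = 1; s <= lim; ++s) {
      double sumE = 0.0;
      if (sddt > 0.0) {
        for (int j = 0; j < k; ++j) { E[j] = mu[j] + sddt * norm_rand(); sumE += E[j]; }
      } else {
        for (int j = 0; j < k; ++j) { E[j] = mu[j]; sumE += E[j]; }
      }
      const double I = f * sumE / k;
      int ncross = 0, cross0 = -1, cross1 = -1;
      for (int j = 0; j < k; ++j) {
        y[j] += E[j] - I;
        if (j < n_choosable && y[j] >= threshold) {
          if (ncross == 0) cross0 = j; else cross1 = j;
          ++ncross;
        }
      }
      if (ncross > 0) {
        int w = cross0;
        if (ncross > 1 && unif_rand() < 0.5) w = cross1;
        ch = w + 1; st = s;
        break;
      }
    }
    choice[i] = ch; step[i] = st; decided[i] = (ch != 0);
  }
  return List::create(_["choice"] = choice, _["step"] = step,
                      _["decided"] = decided);
}
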