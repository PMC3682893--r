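#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the two-state persister process.
// Events and propensities: death of a normal cell (m*n), switch normal ->
// persister (a*n), switch persister -> normal (b*p).  States are recorded at
// the requested grid times (state just before any event at exactly that
// time).  Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_gillespie_two_state(double m, double a, double b,
                                      int n0, int p0, NumericVector t_grid) {
  const int K = t_grid.size();
  IntegerMatrix out(K, 2);
  double t = 0.0;
  long n = n0, p = p0;
  int k = 0;
  RNGScope scope;
  while (k < K) {
    double dn = (m + a) * (double)n;
    double total = dn + b * (double)p;
    double t_next = (total > 0.0) ? t + R::exp_rand() / total : R_PosInf;
    while (k < K && t_grid[k] < t_next) {
      out(k, 0) = (int)n;
      out(k, 1) = (int)p;
      ++k;
    }
    if (k >= K || !R_finite(t_next)) break;
    t = t_next;
    double u = unif_rand() * total;
    if (u < m * (double)n) {
      --n;                       // death of a normal cell
    } else if (u < dn) {
      --n; ++p;                  // normal -> persister
    } else {
      --p; ++n;                  // persister -> normal
    }
  }
  return out;
}
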