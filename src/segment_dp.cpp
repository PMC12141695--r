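#include <Rcpp.h>
using namespace Rcpp;

// Optimal partitioning for piecewise-constant mean segmentation.
// Minimises sum over segments of SSE/sigma2 plus beta per breakpoint.
// Returns 0-based start indices of segments 2..k (i.e. the breakpoints).
// [[Rcpp::export]]
IntegerVector segment_dp_cpp(NumericVector x, double sigma2, double beta,
                             int min_len) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; i++) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> prev(n + 1, 0);
  F[0] = -beta;
  for (int j = min_len; j <= n; j++) {
    double best = R_PosInf;
    int bi = 0;
    for (int i = 0; i + min_len <= j; i++) {
      if (!R_finite(F[i])) continue;
      double len = j - i;
      double s = cs[j] - cs[i];
      double sse = cs2[j] - cs2[i] - s * s / len;
      if (sse < 0) sse = 0;  // numerical guard
      double cand = F[i] + sse / sigma2 + beta;
      if (cand < best) { best = cand; bi = i; }
    }
    F[j] = best;
    prev[j] = bi;
  }
  std::vector<int> bp;
  int j = n;
  while (j > 0) {
    int i = prev[j];
    if (i > 0) bp.push_back(i);
    j = i;
  }
  std::reverse(bp.begin(), bp.end());
  return wrap(bp);
}
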