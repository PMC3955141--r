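#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact two-sided permutation p-value for Spearman's rho.
// Enumerates all n! orderings of ry against fixed rx (feasible to n = 10)
// and counts permutations with |rho| >= |rho_obs| - eps.  Ranks may contain
// ties (average ranks); the permutation distribution conditions on the
// observed tie pattern.
// [[Rcpp::export]]
double spearman_perm_pvalue(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n != ry.size()) stop("length mismatch");
  if (n > 10) stop("exact permutation only supported for n <= 10");

  double mx = mean(rx), my = mean(ry);
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < n; ++i) {
    sx += (rx[i] - mx) * (rx[i] - mx);
    sy += (ry[i] - my) * (ry[i] - my);
  }
  if (sx <= 0.0 || sy <= 0.0) stop("rho undefined for constant ranks");
  double denom = std::sqrt(sx * sy);

  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += (rx[i] - mx) * (ry[i] - my);
  double thr = std::fabs(obs / denom) - 1e-12;

  std::vector<double> perm(ry.begin(), ry.end());
  std::sort(perm.begin(), perm.end());
  long long total = 0, extreme = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (rx[i] - mx) * (perm[i] - my);
    if (std::fabs(s / denom) >= thr) ++extreme;
    ++total;
  } while (std::next_permutation(perm.begin(), perm.end()));
  // with tied ranks the sorted-multiset cycle visits each distinct
  // arrangement once; probabilities remain uniform over arrangements
  return (double)extreme / (double)total;
}
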