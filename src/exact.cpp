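#include <Rcpp.h>
using namespace Rcpp;

// Exact permutation null for the Spearman statistic.
//
// Under permutation of one margin, the Spearman correlation is a fixed
// affine function of S = sum_i rx[i] * ry[perm(i)], so tail counts on S are
// tail counts on rho. Enumerates all n! permutations of ry with Heap's
// algorithm; feasible for n <= 10 (10! = 3,628,800).
//
// Returns counts of permutations with S >= s_obs - tol, S <= s_obs + tol,
// and |S - center| >= |s_obs - center| - tol, plus the total count.
// [[Rcpp::export(name = ".spearman_perm_counts")]]
NumericVector spearman_perm_counts(NumericVector rx, NumericVector ry,
                                   double s_obs, double center) {
  const int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  if (n > 10) stop("exact enumeration limited to n <= 10");
  const double tol = 1e-9;
  std::vector<double> y(ry.begin(), ry.end());
  std::vector<int> c(n, 0);

  double n_ge = 0.0, n_le = 0.0, n_abs = 0.0, n_tot = 0.0;
  const double a_obs = std::fabs(s_obs - center);

  double s = 0.0;
  for (int i = 0; i < n; ++i) s += rx[i] * y[i];
  auto tally = [&](double sv) {
    n_tot += 1.0;
    if (sv >= s_obs - tol) n_ge += 1.0;
    if (sv <= s_obs + tol) n_le += 1.0;
    if (std::fabs(sv - center) >= a_obs - tol) n_abs += 1.0;
  };
  tally(s);

  // Heap's algorithm, iterative; update S incrementally on each swap.
  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      int j = (i % 2 == 0) ? 0 : c[i];
      // swapping y[j] and y[i] changes S by (rx[j]-rx[i])*(y[i]-y[j])
      s += (rx[j] - rx[i]) * (y[i] - y[j]);
      std::swap(y[j], y[i]);
      tally(s);
      ++c[i];
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  return NumericVector::create(n_ge, n_le, n_abs, n_tot);
}
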