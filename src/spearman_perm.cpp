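#include <Rcpp.h>
#include <algorithm>

// Exact permutation null for the Spearman statistic. For fixed rank
// multisets, rho is an affine function of S = sum(rx[i] * ry[perm(i)]), so
// the two-sided p-value only needs the count of permutations whose
// |S - E[S]| reaches the observed deviation. Enumerates all n!
// permutations (n <= 10 in practice, 3.6e6 permutations).

// [[Rcpp::export]]
double spearman_perm_count(Rcpp::NumericVector rx, Rcpp::NumericVector ry,
                           double dev_threshold) {
  int n = rx.size();
  std::vector<double> s(ry.begin(), ry.end());
  std::sort(s.begin(), s.end());
  double mean_rx = 0.0, mean_s = 0.0;
  for (int i = 0; i < n; ++i) {
    mean_rx += rx[i];
    mean_s += s[i];
  }
  mean_rx /= n;
  mean_s /= n;
  const double center = n * mean_rx * mean_s;
  double count = 0.0;
  // std::next_permutation over the sorted multiset walks every distinct
  // arrangement once; multiply by the multiplicity of tied values.
  double dup = 1.0;
  {
    int run = 1;
    for (int i = 1; i < n; ++i) {
      if (s[i] == s[i - 1]) {
        ++run;
        dup *= run;
      } else {
        run = 1;
      }
    }
  }
  do {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += rx[i] * s[i];
    if (std::abs(tot - center) >= dev_threshold) count += 1.0;
  } while (std::next_permutation(s.begin(), s.end()));
  return count * dup;
}
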