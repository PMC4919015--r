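#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Standardized tie-corrected two-sample rank-sum statistic for the pair
// formed by the first m and last n entries of `vals` (length m + n).
// Mid-ranks; variance carries the Dwass-Steel-Critchlow-Fligner tie
// correction. Returns 0 when the variance degenerates (all values tied).
static double pair_z(std::vector<double>& vals, int m, int n) {
  const int N = m + n;
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return vals[a] < vals[b]; });
  std::vector<double> rk(N);
  double tie_sum = 0.0;
  int i = 0;
  while (i < N) {
    int j = i;
    while (j + 1 < N && vals[ord[j + 1]] == vals[ord[i]]) ++j;
    const double t = j - i + 1;
    const double midrank = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) rk[ord[k]] = midrank;
    tie_sum += t * t * t - t;
    i = j + 1;
  }
  double w = 0.0;
  for (int k = m; k < N; ++k) w += rk[k];
  const double ew = n * (N + 1.0) / 2.0;
  const double tie_term = tie_sum / (double(N) * (N - 1.0));
  const double v = m * double(n) / 12.0 * ((N + 1.0) - tie_term);
  if (v <= 0.0) return 0.0;
  return (w - ew) / std::sqrt(v);
}

// Monte-Carlo null of the familywise max statistic: permute the pooled
// observations n_iter times (R's RNG, so set.seed() governs) and record the
// maximum absolute pairwise statistic over all group pairs.
// [[Rcpp::export]]
NumericVector dscf_perm_maxima(NumericVector pooled, IntegerVector sizes,
                               int n_iter) {
  const int N = pooled.size();
  const int k = sizes.size();
  std::vector<int> offset(k + 1, 0);
  for (int g = 0; g < k; ++g) offset[g + 1] = offset[g] + sizes[g];
  if (offset[k] != N) stop("group sizes do not sum to the pooled length");

  std::vector<double> perm(pooled.begin(), pooled.end());
  NumericVector maxima(n_iter);
  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double mx = 0.0;
    for (int u = 0; u < k - 1; ++u) {
      for (int v = u + 1; v < k; ++v) {
        const int m = sizes[u], n = sizes[v];
        std::vector<double> sub(m + n);
        std::copy(perm.begin() + offset[u], perm.begin() + offset[u + 1],
                  sub.begin());
        std::copy(perm.begin() + offset[v], perm.begin() + offset[v + 1],
                  sub.begin() + m);
        const double z = std::fabs(pair_z(sub, m, n));
        if (z > mx) mx = z;
      }
    }
    maxima[it] = mx;
  }
  return maxima;
}
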