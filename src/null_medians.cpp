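#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Medians of random same-size gene sets drawn WITHOUT replacement from one
// sample's expression values. Uses R's RNG (unif_rand) so results are
// reproducible under set.seed(); partial Fisher-Yates per draw.
// [[Rcpp::export(name = ".null_medians_mc")]]
NumericVector null_medians_mc(NumericVector values, int k, int n_draws) {
  const int n = values.size();
  if (k < 1 || k > n) stop("module size out of range");
  std::vector<int> idx(n);
  std::vector<double> draw(k);
  NumericVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    int m = n;
    for (int j = 0; j < k; ++j) {
      int r = j + static_cast<int>(unif_rand() * (m - j));
      if (r >= m) r = m - 1;
      std::swap(idx[j], idx[r]);
      draw[j] = values[idx[j]];
    }
    std::sort(draw.begin(), draw.end());
    out[d] = (k % 2 == 1) ? draw[k / 2]
                          : 0.5 * (draw[k / 2 - 1] + draw[k / 2]);
  }
  return out;
}
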