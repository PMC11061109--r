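#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Count labeled genes having >= 1 labeled neighbor within `window` on the
// same contig. `lab` holds 0-based indices into gene arrays sorted by
// (contig, start); distance between two genes is the number of bases
// strictly between them (overlap -> 0).
static int coloc_count(std::vector<int> &lab, const IntegerVector &contig,
                       const NumericVector &start, const NumericVector &end,
                       double window) {
  const int k = (int)lab.size();
  std::sort(lab.begin(), lab.end());
  std::vector<char> has(k, 0);
  int n_with = 0;
  for (int i = 0; i < k; ++i) {
    const int gi = lab[i];
    for (int j = i + 1; j < k; ++j) {
      const int gj = lab[j];
      if (contig[gj] != contig[gi]) break;  // sorted: contig block ended
      double gap = start[gj] - end[gi] - 1.0;
      if (gap < 0.0) gap = 0.0;
      if (gap <= window) {
        if (!has[i]) { has[i] = 1; ++n_with; }
        if (!has[j]) { has[j] = 1; ++n_with; }
      } else {
        break;  // starts increase within the contig, so gaps only grow
      }
    }
  }
  return n_with;
}

// [[Rcpp::export]]
int coloc_stat_cpp(IntegerVector lab0, IntegerVector contig,
                   NumericVector start, NumericVector end, double window) {
  std::vector<int> lab(lab0.begin(), lab0.end());
  return coloc_count(lab, contig, start, end, window);
}

// Null distribution of the statistic under uniform label reassignment.
// Uses R's RNG (via Rcpp::sample), so results are reproducible under
// set.seed() on the R side.
// [[Rcpp::export]]
IntegerVector coloc_perm_cpp(int K, IntegerVector contig,
                             NumericVector start, NumericVector end,
                             double window, int B) {
  const int N = contig.size();
  IntegerVector out(B);
  std::vector<int> lab(K);
  for (int b = 0; b < B; ++b) {
    IntegerVector s = sample(N, K, false);  // 1-based draw w/o replacement
    for (int i = 0; i < K; ++i) lab[i] = s[i] - 1;
    out[b] = coloc_count(lab, contig, start, end, window);
  }
  return out;
}
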