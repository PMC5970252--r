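#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Pooled midranks per column plus tie diagnostics, in one pass per column:
// returns the n x m midrank matrix, a has-ties flag per column, and the
// tie-correction term sum(t^3 - t) over tied groups.
//
// [[Rcpp::export(name = ".col_rank_info_cpp")]]
List col_rank_info(NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix R(n, m);
  LogicalVector ties(m);
  NumericVector tie_term(m);
  std::vector<int> ord(n);
  for (int j = 0; j < m; ++j) {
    std::iota(ord.begin(), ord.end(), 0);
    const double* col = &X(0, j);
    std::sort(ord.begin(), ord.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    double tt = 0.0;
    bool any_tie = false;
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && col[ord[k + 1]] == col[ord[i]]) ++k;
      const double avg = (i + k) / 2.0 + 1.0;  // midrank of the run i..k
      for (int l = i; l <= k; ++l) R(ord[l], j) = avg;
      const int t = k - i + 1;
      if (t > 1) {
        any_tie = true;
        tt += static_cast<double>(t) * t * t - t;
      }
      i = k + 1;
    }
    ties[j] = any_tie;
    tie_term[j] = tt;
  }
  return List::create(_["ranks"] = R, _["has_ties"] = ties,
                      _["tie_term"] = tie_term);
}

// B uniform n1-subsets of 1..n as a B x n 0/1 indicator matrix (partial
// Fisher-Yates per row, driven by R's RNG so results are seed-reproducible).
//
// [[Rcpp::export(name = ".random_subsets_cpp")]]
NumericMatrix random_subsets(int n, int n1, int B) {
  NumericMatrix Z(B, n);
  std::vector<int> pool(n);
  for (int b = 0; b < B; ++b) {
    std::iota(pool.begin(), pool.end(), 0);
    for (int i = 0; i < n1; ++i) {
      const int j = i + static_cast<int>(R_unif_index(n - i));
      std::swap(pool[i], pool[j]);
      Z(b, pool[i]) = 1.0;
    }
  }
  return Z;
}
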