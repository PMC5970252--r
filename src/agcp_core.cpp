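#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <utility>
#include <vector>

using namespace Rcpp;

// ECDF counts against the null rows 1..nr-1 of v: cnt[b] = #{null <= v[b]}.
// The null queries are the null values themselves, so after one index sort
// every null element's count is the end of its tie run; only the observed
// row 0 needs a search.
static void null_counts(const std::vector<double>& v,
                        std::vector<std::pair<double, int> >& buf,
                        std::vector<int>& cnt) {
  const int nB = static_cast<int>(v.size()) - 1;
  for (int b = 1; b <= nB; ++b) buf[b - 1] = std::make_pair(v[b], b);
  std::sort(buf.begin(), buf.end());
  int i = 0;
  while (i < nB) {
    int j = i;
    while (j + 1 < nB && buf[j + 1].first == buf[i].first) ++j;
    for (int l = i; l <= j; ++l) cnt[buf[l].second] = j + 1;
    i = j + 1;
  }
  int lo = 0, hi = nB;  // #{null <= v[0]}
  while (lo < hi) {
    const int mid = (lo + hi) / 2;
    if (buf[mid].first <= v[0]) lo = mid + 1; else hi = mid;
  }
  cnt[0] = lo;
}

// Shared back half of the AGCP computation: from the (B+1) x S matrix of
// elementary-bin Fisher sums (row 0 observed, rows 1..B permuted), form the
// two bin sums for every ordered threshold pair by left-to-right
// accumulation, map them through the (B+1)-denominator empirical CDFs of
// rows 1..B, combine, maximize over pairs, and count the permutation
// p-value. The GCP transform only sees ECDF counts, so
// h(c) = -2 log1p(-c/(B+1)) is tabulated once.
static List pair_loop(const NumericMatrix& D, const int S, const bool add_one) {
  const int nr = D.nrow();
  const int B = nr - 1;
  const double denom = static_cast<double>(B) + 1.0;
  std::vector<double> h(B + 1);
  for (int c = 0; c <= B; ++c) h[c] = -2.0 * std::log1p(-c / denom);

  // GCP for a pair is -2 log of (B+1-c1)(B+1-c2)/(B+1)^2, a strictly
  // decreasing function of the integer product (B+1-c1)(B+1-c2). Maximizing
  // over pairs and comparing the maxima across rows is therefore done on
  // that exact integer scale: distinct count pairs can share the same
  // product (an exact tie), and deciding such ties in floating point would
  // make the permutation p-value depend on rounding order.
  const int npairs = S * (S - 1) / 2;
  std::vector<double> cum(nr), t2(nr);
  std::vector<std::pair<double, int> > buf(B);
  std::vector<int> cnt(nr), c1(nr);
  std::vector<long long> bestq(nr, LLONG_MAX);
  NumericVector agcp(nr);
  NumericVector gcp0(npairs);
  int arg0 = 0;
  int r = 0;
  for (int a = 0; a < S - 1; ++a) {
    // T1 = D[,0] + ... + D[,a], left to right
    for (int b = 0; b < nr; ++b) {
      cum[b] = (a == 0) ? D(b, 0) : cum[b] + D(b, a);
    }
    // first-bin counts are shared by every pair with this lower threshold
    null_counts(cum, buf, c1);
    std::fill(t2.begin(), t2.end(), 0.0);
    for (int c = a + 1; c < S; ++c) {
      // T2 = D[,a+1] + ... + D[,c], left to right
      for (int b = 0; b < nr; ++b) t2[b] += D(b, c);
      null_counts(t2, buf, cnt);
      for (int b = 0; b < nr; ++b) {
        const long long q =
            static_cast<long long>(B + 1 - c1[b]) * (B + 1 - cnt[b]);
        if (b == 0) gcp0[r] = h[c1[0]] + h[cnt[0]];
        if (q < bestq[b]) {  // strict: ties keep the first (smallest) pair
          bestq[b] = q;
          agcp[b] = h[c1[b]] + h[cnt[b]];
          if (b == 0) arg0 = r;
        }
      }
      ++r;
    }
  }

  int n_ge = 0;
  for (int b = 1; b < nr; ++b) {
    if (bestq[b] <= bestq[0]) ++n_ge;  // AGCP_b >= AGCP_0, exactly
  }
  const double pvalue = add_one ? (n_ge + 1.0) / (B + 1.0)
                                : static_cast<double>(n_ge) / B;

  NumericVector agcp_null(B);
  for (int b = 1; b < nr; ++b) agcp_null[b - 1] = agcp[b];

  return List::create(
      _["agcp0"] = agcp[0],
      _["agcp_null"] = agcp_null,
      _["gcp_by_pair"] = gcp0,
      _["argmax"] = arg0 + 1,
      _["pvalue"] = pvalue);
}

// Generic kernel: row 0 of P holds the observed marginal p-values, rows
// 1..B the permuted ones; L holds the matching Fisher terms -2 log p.
// Elementary bin sums are accumulated in column order, bitwise identical to
// rowSums over a masked matrix in R, so exact permutation ties are
// implementation-independent.
//
// [[Rcpp::export(name = ".agcp_core_cpp")]]
List agcp_core_cpp(NumericMatrix P, NumericMatrix L, NumericVector xi,
                   bool add_one) {
  const int nr = P.nrow();
  const int S = xi.size();
  const int m = P.ncol();
  if (nr < 2) stop("need at least one permutation row");
  if (L.nrow() != nr || L.ncol() != m) stop("P and L must share dimensions");

  NumericMatrix D(nr, S);
  for (int k = 0; k < m; ++k) {
    for (int b = 0; b < nr; ++b) {
      const double p = P(b, k);
      if (!(p > 0)) stop("p-values must be strictly positive");
      int s = 0;  // elementary bin: xi_{s-1} <= p < xi_s
      while (s < S && p >= xi[s]) ++s;
      if (s < S) D(b, s) += L(b, k);
    }
  }
  return pair_loop(D, S, add_one);
}

// Rank-sum fast path: for tie-free columns the group-1 rank sum is integer,
// so the p-value's elementary bin and Fisher term are pure table lookups in
// U = W - n1(n1+1)/2. bin[u] is the 0-based elementary bin (== S when the
// p-value falls outside every bin), ltab[u] the matching -2 log p.
//
// [[Rcpp::export(name = ".agcp_ranksum_cpp")]]
List agcp_ranksum_cpp(NumericMatrix W, double offset, IntegerVector bin,
                      NumericVector ltab, int S, bool add_one) {
  const int nr = W.nrow();
  const int m = W.ncol();
  const int umax = bin.size() - 1;
  if (nr < 2) stop("need at least one permutation row");

  // fold bin and Fisher term into one stride-ready lookup
  std::vector<int> dcol(umax + 1);
  for (int u = 0; u <= umax; ++u) {
    dcol[u] = (bin[u] < S) ? bin[u] * nr : -1;
  }
  NumericMatrix D(nr, S);
  double* dp = D.begin();
  const double* lt = ltab.begin();
  for (int k = 0; k < m; ++k) {
    const double* wk = &W(0, k);
    for (int b = 0; b < nr; ++b) {
      const int u = static_cast<int>(wk[b] - offset + 0.5);
      if (u < 0 || u > umax) stop("rank sum outside the attainable range");
      const int d = dcol[u];
      if (d >= 0) dp[d + b] += lt[u];
    }
  }
  return pair_loop(D, S, add_one);
}
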