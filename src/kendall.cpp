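#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Kendall tau-b by direct pair enumeration.
// n is small here (neighborhood sizes, <= a few hundred), and the y vector is
// a set of small integer hop counts, so ties in y are the norm: the tie
// correction (C - D) / sqrt((n0 - n1)(n0 - n2)) is essential, not optional.
// Returns NA when all pairs are tied in x or in y (tau undefined).
static double tau_b_core(const double* x, const double* y, const int n) {
  long long conc = 0, disc = 0, tie_x = 0, tie_y = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      if (dx == 0.0) ++tie_x;
      if (dy == 0.0) ++tie_y;
      if (dx != 0.0 && dy != 0.0) {
        if ((dx > 0.0) == (dy > 0.0)) ++conc; else ++disc;
      }
    }
  }
  const long long n0 = (long long)n * (n - 1) / 2;
  const double denom = std::sqrt((double)(n0 - tie_x)) *
                       std::sqrt((double)(n0 - tie_y));
  if (denom == 0.0) return NA_REAL;
  return (double)(conc - disc) / denom;
}

// [[Rcpp::export]]
double tau_b_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 observations");
  return tau_b_core(REAL(x), REAL(y), n);
}

// tau-b of each column of X against a fixed y; exact pair enumeration.
// [[Rcpp::export]]
NumericVector tau_b_cols_cpp(NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), B = X.ncol();
  if (n != y.size()) stop("nrow(X) must equal length(y)");
  if (n < 2) stop("need at least 2 observations");
  NumericVector out(B);
  const double* yp = REAL(y);
  for (int b = 0; b < B; ++b) {
    out[b] = tau_b_core(&X(0, b), yp, n);
  }
  return out;
}

// Kendall tau-b over *nested* neighborhoods, one column at a time.
//
// Rows of X are ordered by non-decreasing distance group; group_sizes gives
// the run lengths of equal-distance blocks. For each column x and each group
// prefix k, returns tau_b(x[1..m_k], d[1..m_k]) where m_k = cumulative size.
// Because distances are constant within a group and strictly increasing
// across groups, concordance counts only involve cross-group pairs, which a
// single sweep with prefix counts over value ranks accumulates in
// O(n log n) per column — this makes the label-permutation null affordable
// at every radius simultaneously.
// [[Rcpp::export]]
NumericMatrix tau_b_nested_cpp(NumericMatrix X, IntegerVector group_sizes) {
  const int n = X.nrow(), B = X.ncol(), K = group_sizes.size();
  long long total = 0;
  for (int k = 0; k < K; ++k) {
    if (group_sizes[k] < 1) stop("group sizes must be positive");
    total += group_sizes[k];
  }
  if (total != n) stop("group sizes must sum to nrow(X)");
  NumericMatrix out(K, B);
  std::vector<double> sorted(n);
  std::vector<int> rk(n);
  for (int b = 0; b < B; ++b) {
    const double* x = &X(0, b);
    // dense ranks of this column's values
    sorted.assign(x, x + n);
    std::sort(sorted.begin(), sorted.end());
    sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
    const int nu = (int)sorted.size();
    for (int i = 0; i < n; ++i) {
      rk[i] = (int)(std::lower_bound(sorted.begin(), sorted.end(), x[i]) -
                    sorted.begin());
    }
    std::vector<long long> tree(nu + 1, 0);
    auto bit_add = [&](int i) { for (++i; i <= nu; i += i & -i) ++tree[i]; };
    auto bit_sum = [&](int i) {  // count of inserted values with rank <= i
      long long s = 0;
      for (++i; i > 0; i -= i & -i) s += tree[i];
      return s;
    };
    long long S = 0, tie_x = 0, tie_y = 0, m = 0;
    int pos = 0;
    for (int k = 0; k < K; ++k) {
      const int s_k = group_sizes[k];
      // cross-group contributions of this block (earlier blocks have
      // strictly smaller distance)
      for (int i = pos; i < pos + s_k; ++i) {
        const long long le = bit_sum(rk[i]);
        const long long lt = rk[i] > 0 ? bit_sum(rk[i] - 1) : 0;
        const long long eq = le - lt;
        S += lt - (m - le);   // concordant minus discordant
        tie_x += eq;          // tied in x across groups
      }
      // within-block pairs: all tied in y; count those also tied in x
      tie_y += (long long)s_k * (s_k - 1) / 2;
      for (int i = pos; i < pos + s_k; ++i) {
        for (int j = i + 1; j < pos + s_k; ++j) {
          if (rk[i] == rk[j]) ++tie_x;
        }
      }
      for (int i = pos; i < pos + s_k; ++i) bit_add(rk[i]);
      m += s_k;
      pos += s_k;
      const long long n0 = m * (m - 1) / 2;
      const double denom = std::sqrt((double)(n0 - tie_x)) *
                           std::sqrt((double)(n0 - tie_y));
      out(k, b) = denom == 0.0 ? NA_REAL : (double)S / denom;
    }
  }
  return out;
}
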