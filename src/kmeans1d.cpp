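#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Globally optimal 1-D k-means by dynamic programming over the sorted
// sample (optimal clusters are contiguous in sorted order).  Each DP layer
// is filled by divide-and-conquer exploiting the monotonicity of the
// optimal split position, so the whole fit is O(k n log n).

namespace {

std::vector<double> S1, S2;  // prefix sums of centred data and its square

inline double seg_cost(int i, int j) {  // within-SS of x[i..j], 0-based incl.
  double s = S1[j + 1] - S1[i];
  double q = S2[j + 1] - S2[i];
  double w = q - s * s / (j - i + 1);
  return w > 0.0 ? w : 0.0;
}

void fill_layer(const std::vector<double> &prev, std::vector<double> &cur,
                std::vector<int> &split, int jlo, int jhi, int ilo, int ihi) {
  if (jlo > jhi) return;
  int jm = (jlo + jhi) / 2;
  double best = std::numeric_limits<double>::infinity();
  int arg = ilo;
  int top = std::min(jm, ihi);
  for (int i = ilo; i <= top; ++i) {
    double c = prev[i - 1] + seg_cost(i, jm);
    if (c < best) {
      best = c;
      arg = i;
    }
  }
  cur[jm] = best;
  split[jm] = arg;
  fill_layer(prev, cur, split, jlo, jm - 1, ilo, arg);
  fill_layer(prev, cur, split, jm + 1, jhi, arg, ihi);
}

}  // namespace

// [[Rcpp::export(name = ".kmeans1d_cpp")]]
Rcpp::List kmeans1d_cpp(Rcpp::NumericVector x_sorted, int k) {
  const int n = x_sorted.size();
  if (k < 1 || k > n) Rcpp::stop("k must be between 1 and n");

  // centre the data for numerically stable prefix sums
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x_sorted[i];
  mu /= n;
  S1.assign(n + 1, 0.0);
  S2.assign(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double z = x_sorted[i] - mu;
    S1[i + 1] = S1[i] + z;
    S2[i + 1] = S2[i] + z * z;
  }

  std::vector<double> prev(n), cur(n);
  std::vector<std::vector<int> > splits(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) prev[j] = seg_cost(0, j);
  for (int q = 1; q < k; ++q) {
    fill_layer(prev, cur, splits[q], 0, n - 1, q, n - 1);
    // clusters must be non-empty: positions j < q are invalid for q+1
    // clusters; fill_layer is only consulted for j >= q below
    std::swap(prev, cur);
  }

  // backtrack cluster boundaries
  std::vector<int> starts(k);
  int j = n - 1;
  for (int q = k - 1; q >= 1; --q) {
    starts[q] = splits[q][j];
    j = splits[q][j] - 1;
  }
  starts[0] = 0;

  Rcpp::IntegerVector assign(n);
  Rcpp::NumericVector centres(k), wss(k), sizes(k);
  double total = 0.0;
  for (int q = 0; q < k; ++q) {
    int a = starts[q];
    int b = (q + 1 < k) ? starts[q + 1] - 1 : n - 1;
    double s = 0.0;
    for (int i = a; i <= b; ++i) {
      assign[i] = q + 1;
      s += x_sorted[i];
    }
    sizes[q] = b - a + 1;
    centres[q] = s / (b - a + 1);
    wss[q] = seg_cost(a, b);
    total += wss[q];
  }

  return Rcpp::List::create(Rcpp::Named("assignments") = assign,
                            Rcpp::Named("centres") = centres,
                            Rcpp::Named("withinss") = wss,
                            Rcpp::Named("sizes") = sizes,
                            Rcpp::Named("tot_withinss") = total,
                            Rcpp::Named("starts") = starts);
}
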