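#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Hartigan's dip statistic for a sorted sample.
//
// The dip is half the smallest sup-norm distance between the empirical CDF
// and the class of unimodal distribution functions.  It is located by the
// classical modal-interval iteration: on the current candidate modal
// interval compute the greatest convex minorant (GCM) of the lower CDF
// corners and the least concave majorant (LCM) of the upper corners, take
// the largest vertical gap between the two hulls, shrink the modal interval
// to the hull touch points bracketing that gap, and accumulate the
// deviations of the empirical CDF from the hulls outside the new interval.
// Ties are collapsed to distinct abscissas carrying both corner values, so
// the statistic is exact for discrete samples as well.

namespace {

struct Hull {
  std::vector<int> v;  // touch-point indices, ascending
};

// value of the piecewise-linear hull at index j (xd[j]); `pos` is a hint
// for the segment search and is advanced monotonically by the callers.
inline double hull_val(const Hull &h, const std::vector<double> &xd,
                       const std::vector<double> &y, int j, int &pos) {
  while (pos + 1 < (int)h.v.size() && h.v[pos + 1] < j) ++pos;
  int a = h.v[pos];
  if (a == j) return y[a];
  int b = h.v[pos + 1];
  if (b == j) return y[b];
  double t = (xd[j] - xd[a]) / (xd[b] - xd[a]);
  return y[a] + t * (y[b] - y[a]);
}

// lower convex hull of (xd[j], y[j]) for j in [lo, hi]
Hull lower_hull(const std::vector<double> &xd, const std::vector<double> &y,
                int lo, int hi) {
  Hull h;
  for (int j = lo; j <= hi; ++j) {
    while (h.v.size() >= 2) {
      int b = h.v[h.v.size() - 1], a = h.v[h.v.size() - 2];
      // pop b if it lies on or above segment a--j
      double cross = (xd[b] - xd[a]) * (y[j] - y[a]) -
                     (y[b] - y[a]) * (xd[j] - xd[a]);
      if (cross >= 0.0) break;
      h.v.pop_back();
    }
    h.v.push_back(j);
  }
  return h;
}

// upper concave hull
Hull upper_hull(const std::vector<double> &xd, const std::vector<double> &y,
                int lo, int hi) {
  Hull h;
  for (int j = lo; j <= hi; ++j) {
    while (h.v.size() >= 2) {
      int b = h.v[h.v.size() - 1], a = h.v[h.v.size() - 2];
      double cross = (xd[b] - xd[a]) * (y[j] - y[a]) -
                     (y[b] - y[a]) * (xd[j] - xd[a]);
      if (cross <= 0.0) break;
      h.v.pop_back();
    }
    h.v.push_back(j);
  }
  return h;
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector x_sorted) {
  const int n = x_sorted.size();
  if (n < 2) return 0.0;

  // collapse ties: distinct abscissas with lower/upper CDF corners
  std::vector<double> xd, lo_c, hi_c;
  xd.reserve(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x_sorted[j + 1] == x_sorted[i]) ++j;
    xd.push_back(x_sorted[i]);
    lo_c.push_back((double)i / n);
    hi_c.push_back((double)(j + 1) / n);
    i = j + 1;
  }
  const int m = (int)xd.size();
  if (m == 1) return 0.0;  // degenerate sample: perfectly unimodal

  int low = 0, high = m - 1;
  double d = 1.0 / n;  // twice the minimal dip for a non-degenerate sample

  for (int iter = 0; iter < 2 * m + 10; ++iter) {
    Hull g = lower_hull(xd, lo_c, low, high);
    Hull l = upper_hull(xd, hi_c, low, high);

    // largest gap between the LCM and GCM curves; it is attained at a
    // touch point of one of the hulls
    double dcross = -1.0;
    int ig = low, ih = high;
    {
      int pos = 0;
      for (size_t t = 0; t < g.v.size(); ++t) {
        int j = g.v[t];
        double gap = hull_val(l, xd, hi_c, j, pos) - lo_c[j];
        if (gap > dcross) {
          dcross = gap;
          ig = j;
          ih = l.v[std::min((size_t)pos + 1, l.v.size() - 1)];
          if (l.v[pos] >= j) ih = l.v[pos];
        }
      }
    }
    {
      int pos = 0;
      for (size_t t = 0; t < l.v.size(); ++t) {
        int j = l.v[t];
        double gap = hi_c[j] - hull_val(g, xd, lo_c, j, pos);
        if (gap > dcross) {
          dcross = gap;
          ih = j;
          ig = g.v[pos];
          if (g.v[std::min((size_t)pos + 1, g.v.size() - 1)] <= j)
            ig = g.v[std::min((size_t)pos + 1, g.v.size() - 1)];
        }
      }
    }

    if (dcross <= d) break;

    // deviations of the empirical CDF from the hulls outside the new
    // modal interval
    double dl = 0.0, du = 0.0;
    {
      int pos = 0;
      for (int j = low; j <= ig; ++j) {
        double dev = hi_c[j] - hull_val(g, xd, lo_c, j, pos);
        if (dev > dl) dl = dev;
      }
    }
    {
      int pos = 0;
      for (int j = ih; j <= high; ++j) {
        double dev = hull_val(l, xd, hi_c, j, pos) - lo_c[j];
        if (dev > du) du = dev;
      }
    }
    d = std::max(d, std::max(dl, du));

    if (ig <= low && ih >= high) break;  // no progress: interval cannot shrink
    low = ig;
    high = ih;
    if (low >= high) break;
  }

  return d / 2.0;
}

// Monte-Carlo null draws for the dip test: `reps` samples of size n from
// U(0,1) using R's RNG stream, returning each null dip.
// [[Rcpp::export(name = ".dip_null_cpp")]]
Rcpp::NumericVector dip_null_cpp(int n, int reps) {
  Rcpp::NumericVector out(reps);
  std::vector<double> u(n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) u[i] = R::unif_rand();
    std::sort(u.begin(), u.end());
    Rcpp::NumericVector xs(u.begin(), u.end());
    out[r] = dip_stat_cpp(xs);
  }
  return out;
}
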