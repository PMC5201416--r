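#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dip statistic: sup-norm distance between the empirical CDF of a sample
// and the closest unimodal CDF (convex below the mode, concave above).
//
// All arithmetic is carried out in rank units. Point i (0-based) carries
// rank r = i+1; the ECDF equals r/n at x_i and (r-1)/n just left of it.
// The greatest convex minorant of the step ECDF passes below the
// left-limit points (x_i, r-1), the least concave majorant above the
// right-limit points (x_i, r). Expressing both against hulls of the rank
// points (x_i, r), each step correction appears as "+1":
//   left-flank deviation  = max_i [ r_i - gcm(x_i) ] + 1
//   right-flank deviation = max_i [ lcm(x_i) - (r_i - 1) ]
//   modal-gap requirement = max   [ lcm - gcm ] + 1
// The candidate modal interval is shrunk towards the largest hull gap;
// flank deviations accumulate into D, and dip = D / (2n) with D >= 1,
// so dip >= 1/(2n) always (attained by an equally spaced sample).

namespace {

struct Hull {
  std::vector<int> v;  // vertex indices into the data, ascending
  double at(const std::vector<double>& x, const std::vector<double>& y,
            int idx, size_t& seg) const {
    while (seg + 1 < v.size() && v[seg + 1] < idx) ++seg;
    if (seg + 1 >= v.size()) return y[v[seg]];
    int a = v[seg], b = v[seg + 1];
    if (x[b] <= x[a]) return y[b];
    double t = (x[idx] - x[a]) / (x[b] - x[a]);
    return y[a] + t * (y[b] - y[a]);
  }
};

}  // namespace

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs) {
  int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = i + 1.0;

  int lo = 0, hi = n - 1;
  double D = 1.0;

  for (int iter = 0; iter <= n; ++iter) {
    Hull g, l;
    for (int i = lo; i <= hi; ++i) {
      while (g.v.size() >= 2) {
        int b = g.v[g.v.size() - 1], a = g.v[g.v.size() - 2];
        if ((x[i] - x[a]) * (y[b] - y[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
          g.v.pop_back();
        else break;
      }
      g.v.push_back(i);
      while (l.v.size() >= 2) {
        int b = l.v[l.v.size() - 1], a = l.v[l.v.size() - 2];
        if ((x[i] - x[a]) * (y[b] - y[a]) <= (y[i] - y[a]) * (x[b] - x[a]))
          l.v.pop_back();
        else break;
      }
      l.v.push_back(i);
    }

    // largest vertical gap between the hulls, with its bracketing interval
    double dgap = 0.0;
    int mlo = lo, mhi = hi;
    {
      size_t seg = 0;
      for (size_t k = 0; k < l.v.size(); ++k) {
        int vtx = l.v[k];
        double gv = g.at(x, y, vtx, seg);
        double dev = y[vtx] - gv;
        if (dev > dgap) { dgap = dev; mlo = g.v[seg]; mhi = vtx; }
      }
    }
    {
      size_t seg = 0;
      for (size_t k = 0; k < g.v.size(); ++k) {
        int vtx = g.v[k];
        double lv = l.at(x, y, vtx, seg);
        double dev = lv - y[vtx];
        if (dev > dgap) {
          dgap = dev;
          mlo = vtx;
          mhi = (seg + 1 < l.v.size()) ? l.v[seg + 1] : l.v[seg];
        }
      }
    }

    if (dgap + 1.0 <= D) break;

    // flank deviations of the ECDF outside the shrunk modal interval
    double dl = 0.0;
    {
      size_t seg = 0;
      for (int i = lo; i <= mlo; ++i) {
        double gv = g.at(x, y, i, seg);
        if (y[i] - gv > dl) dl = y[i] - gv;
      }
      dl += 1.0;
    }
    double du = 0.0;
    {
      size_t seg = 0;
      for (int i = lo; i <= hi; ++i) {
        double lv = l.at(x, y, i, seg);
        if (i < mhi) continue;
        double dev = lv - (y[i] - 1.0);
        if (dev > du) du = dev;
      }
    }
    double Dnew = std::max(dl, du);
    if (Dnew > D) D = Dnew;
    if (mlo <= lo && mhi >= hi) break;
    if (mlo >= mhi) break;
    lo = mlo; hi = mhi;
  }
  return D / (2.0 * n);
}
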