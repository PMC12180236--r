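#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact bounded-Voronoi adjacency. Cells i and j share an edge iff a point
// exists on the perpendicular bisector of (i, j) that is (a) inside the
// padded bounding box and (b) no farther from i than from any other site.
// The bisector is parameterized as M + t*D (M midpoint, D the bisector
// direction); every other site k and every box side contributes a linear
// constraint on t, so adjacency reduces to a 1-D interval intersection.
// [[Rcpp::export]]
LogicalMatrix voronoi_adjacency(NumericVector x, NumericVector y,
                                double xmin, double xmax,
                                double ymin, double ymax) {
  int n = x.size();
  LogicalMatrix adj(n, n);
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      // direction along the bisector = rotated (j - i)
      double dx = -(y[j] - y[i]), dy = x[j] - x[i];
      double norm = std::sqrt(dx * dx + dy * dy);
      if (norm < eps) continue;  // coincident points
      dx /= norm; dy /= norm;
      double tlo = -1e18, thi = 1e18;
      // bounding box: xmin <= mx + t*dx <= xmax (same for y)
      if (std::fabs(dx) > eps) {
        double t1 = (xmin - mx) / dx, t2 = (xmax - mx) / dx;
        tlo = std::max(tlo, std::min(t1, t2));
        thi = std::min(thi, std::max(t1, t2));
      } else if (mx < xmin || mx > xmax) continue;
      if (std::fabs(dy) > eps) {
        double t1 = (ymin - my) / dy, t2 = (ymax - my) / dy;
        tlo = std::max(tlo, std::min(t1, t2));
        thi = std::min(thi, std::max(t1, t2));
      } else if (my < ymin || my > ymax) continue;
      bool ok = tlo <= thi + eps;
      // half-plane per other site k: |p - i|^2 <= |p - k|^2
      // => linear in t: a*t <= b with
      // a = 2*D.(k - i), b = |k - m_i|^2 - |i - m_i|^2 evaluated at M
      for (int k = 0; ok && k < n; ++k) {
        if (k == i || k == j) continue;
        double a = 2.0 * (dx * (x[k] - x[i]) + dy * (y[k] - y[i]));
        double b = (x[k] - mx) * (x[k] - mx) + (y[k] - my) * (y[k] - my)
                 - (x[i] - mx) * (x[i] - mx) - (y[i] - my) * (y[i] - my);
        if (std::fabs(a) < eps) {
          if (b < -eps) ok = false;
        } else if (a > 0) {
          thi = std::min(thi, b / a);
        } else {
          tlo = std::max(tlo, b / a);
        }
        if (tlo > thi + eps) ok = false;
      }
      if (ok && thi - tlo > eps) {
        adj(i, j) = true;
        adj(j, i) = true;
      }
    }
  }
  return adj;
}
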