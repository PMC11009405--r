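#include <Rcpp.h>
using namespace Rcpp;

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool on_seg(double ax, double ay, double bx, double by,
                          double px, double py) {
  return std::min(ax, bx) <= px && px <= std::max(ax, bx) &&
         std::min(ay, by) <= py && py <= std::max(ay, by);
}

static bool seg_intersect(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  double d1 = orient(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = orient(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = orient(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = orient(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  if (d1 == 0 && on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) return true;
  if (d2 == 0 && on_seg(q1x, q1y, q2x, q2y, p2x, p2y)) return true;
  if (d3 == 0 && on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) return true;
  if (d4 == 0 && on_seg(p1x, p1y, p2x, p2y, q2x, q2y)) return true;
  return false;
}

// True iff any two non-adjacent segments of the polyline (x, y) intersect.
// Exact orientation test with bounding-box rejection.
// [[Rcpp::export]]
bool c_polyline_self_intersects(NumericVector x, NumericVector y) {
  int n = x.size() - 1; // segments
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    double xi0 = std::min(x[i], x[i + 1]), xi1 = std::max(x[i], x[i + 1]);
    double yi0 = std::min(y[i], y[i + 1]), yi1 = std::max(y[i], y[i + 1]);
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1 &&
          x[0] == x[n] && y[0] == y[n])
        continue; // closed curve endpoints share a vertex
      if (std::max(x[j], x[j + 1]) < xi0 || std::min(x[j], x[j + 1]) > xi1 ||
          std::max(y[j], y[j + 1]) < yi0 || std::min(y[j], y[j + 1]) > yi1)
        continue;
      if (seg_intersect(x[i], y[i], x[i + 1], y[i + 1], x[j], y[j],
                        x[j + 1], y[j + 1]))
        return true;
    }
  }
  return false;
}
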