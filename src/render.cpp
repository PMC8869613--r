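#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chord-length image of a cylinder (tube) over a regular object-plane grid.
// Pixel (r, c) sits at x = x0 + (c-1)*dx, y = y0 + (r-1)*dy (mm). The tube
// centerline is a polyline (n x 2, mm). Intensity is the transverse chord
// length 2*sqrt(rad^2 - s^2) at perpendicular distance s, i.e. the line
// integral through the cylinder; supersample^2 sub-pixel offsets are
// averaged so sub-pixel tube positions are rendered smoothly.
// [[Rcpp::export(name = ".renderTubeCpp")]]
NumericMatrix renderTubeCpp(int nrow, int ncol, double x0, double dx,
                            double y0, double dy, NumericMatrix poly,
                            double rad, int supersample) {
  NumericMatrix out(nrow, ncol);
  const int nseg = poly.nrow() - 1;
  const int ss = supersample < 1 ? 1 : supersample;
  const double margin = rad + std::fabs(dx) + std::fabs(dy);
  // polyline bounding box to skip far pixels
  double bx0 = R_PosInf, bx1 = R_NegInf, by0 = R_PosInf, by1 = R_NegInf;
  for (int i = 0; i <= nseg; ++i) {
    bx0 = std::min(bx0, poly(i, 0)); bx1 = std::max(bx1, poly(i, 0));
    by0 = std::min(by0, poly(i, 1)); by1 = std::max(by1, poly(i, 1));
  }
  for (int c = 0; c < ncol; ++c) {
    const double px = x0 + c * dx;
    if (px < bx0 - margin || px > bx1 + margin) continue;
    for (int r = 0; r < nrow; ++r) {
      const double py = y0 + r * dy;
      if (py < by0 - margin || py > by1 + margin) continue;
      double acc = 0;
      for (int sy = 0; sy < ss; ++sy) {
        for (int sx = 0; sx < ss; ++sx) {
          const double qx = px + ((sx + 0.5) / ss - 0.5) * dx;
          const double qy = py + ((sy + 0.5) / ss - 0.5) * dy;
          double d2 = R_PosInf;
          for (int i = 0; i < nseg; ++i) {
            const double ax = poly(i, 0), ay = poly(i, 1);
            const double bx = poly(i + 1, 0), by = poly(i + 1, 1);
            const double vx = bx - ax, vy = by - ay;
            const double L2 = vx * vx + vy * vy;
            double t = L2 > 0 ? ((qx - ax) * vx + (qy - ay) * vy) / L2 : 0.0;
            t = t < 0 ? 0 : (t > 1 ? 1 : t);
            const double ex = qx - (ax + t * vx), ey = qy - (ay + t * vy);
            const double dd = ex * ex + ey * ey;
            if (dd < d2) d2 = dd;
          }
          if (d2 < rad * rad) acc += 2.0 * std::sqrt(rad * rad - d2);
        }
      }
      out(r, c) = acc / (ss * ss);
    }
  }
  return out;
}
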