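#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Convex-polygon machinery for rotated rectangles.
// Boxes arrive as rows (x, y, w, h, theta) in the long-edge convention:
// image coordinates, y down, theta clockwise-positive from the x-axis.

namespace {

struct Pt { double x, y; };

const double COLLINEAR_TOL = 1e-9;

void box_corners(const double *b, Pt out[4]) {
  double c = std::cos(b[4]), s = std::sin(b[4]);
  double hw = b[2] / 2.0, hh = b[3] / 2.0;
  // clockwise winding in image coordinates (y down)
  const double ox[4] = {-hw,  hw,  hw, -hw};
  const double oy[4] = {-hh, -hh,  hh,  hh};
  for (int i = 0; i < 4; ++i) {
    out[i].x = b[0] + c * ox[i] - s * oy[i];
    out[i].y = b[1] + s * ox[i] + c * oy[i];
  }
}

inline double cross_side(const Pt &a, const Pt &b, const Pt &p) {
  return (b.x - a.x) * (p.y - a.y) - (b.y - a.y) * (p.x - a.x);
}

// Sutherland-Hodgman: clip subject polygon by the half-plane left of edge a->b
// (interior side for clockwise winding with y down).
void clip_edge(const std::vector<Pt> &subj, const Pt &a, const Pt &b,
               std::vector<Pt> &out) {
  out.clear();
  size_t n = subj.size();
  if (n == 0) return;
  for (size_t i = 0; i < n; ++i) {
    const Pt &cur = subj[i];
    const Pt &nxt = subj[(i + 1) % n];
    double dc = cross_side(a, b, cur);
    double dn = cross_side(a, b, nxt);
    bool cin = dc >= -COLLINEAR_TOL;
    bool nin = dn >= -COLLINEAR_TOL;
    if (cin) out.push_back(cur);
    if (cin != nin) {
      double t = dc / (dc - dn);
      Pt ip;
      ip.x = cur.x + t * (nxt.x - cur.x);
      ip.y = cur.y + t * (nxt.y - cur.y);
      out.push_back(ip);
    }
  }
}

double shoelace(const std::vector<Pt> &p) {
  double a = 0.0;
  size_t n = p.size();
  if (n < 3) return 0.0;
  for (size_t i = 0; i < n; ++i) {
    const Pt &u = p[i];
    const Pt &v = p[(i + 1) % n];
    a += u.x * v.y - v.x * u.y;
  }
  return std::fabs(a) / 2.0;
}

double inter_area(const double *ba, const double *bb) {
  // cheap reject via circumscribed extents
  double ra = std::hypot(ba[2], ba[3]) / 2.0;
  double rb = std::hypot(bb[2], bb[3]) / 2.0;
  if (std::fabs(ba[0] - bb[0]) > ra + rb || std::fabs(ba[1] - bb[1]) > ra + rb)
    return 0.0;
  Pt qa[4], qb[4];
  box_corners(ba, qa);
  box_corners(bb, qb);
  std::vector<Pt> poly(qa, qa + 4), tmp;
  for (int e = 0; e < 4; ++e) {
    clip_edge(poly, qb[e], qb[(e + 1) % 4], tmp);
    poly.swap(tmp);
    if (poly.empty()) return 0.0;
  }
  return shoelace(poly);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_intersection_matrix(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  NumericMatrix out(n, m);
  std::vector<double> ra(5), rb(5);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 5; ++k) ra[k] = a(i, k);
    for (int j = 0; j < m; ++j) {
      for (int k = 0; k < 5; ++k) rb[k] = b(j, k);
      out(i, j) = inter_area(ra.data(), rb.data());
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_intersection_pairs(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow();
  if (b.nrow() != n) stop("row mismatch");
  NumericVector out(n);
  std::vector<double> ra(5), rb(5);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 5; ++k) { ra[k] = a(i, k); rb[k] = b(i, k); }
    out[i] = inter_area(ra.data(), rb.data());
  }
  return out;
}

// Greedy score-descending rotated NMS. Ties in score keep ascending original
// index first (stable). Returns kept indices (1-based) in descending score.
// [[Rcpp::export]]
IntegerVector cpp_rotated_nms(NumericMatrix boxes, NumericVector scores,
                              double iou_thr) {
  int n = boxes.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int i, int j) {
    return scores[i] > scores[j];
  });
  std::vector<bool> removed(n, false);
  std::vector<int> keep;
  std::vector<double> bi(5), bj(5);
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (removed[i]) continue;
    keep.push_back(i + 1);
    for (int k = 0; k < 5; ++k) bi[k] = boxes(i, k);
    double ai = boxes(i, 2) * boxes(i, 3);
    for (int oj = oi + 1; oj < n; ++oj) {
      int j = ord[oj];
      if (removed[j]) continue;
      for (int k = 0; k < 5; ++k) bj[k] = boxes(j, k);
      double inter = inter_area(bi.data(), bj.data());
      double uni = ai + boxes(j, 2) * boxes(j, 3) - inter;
      if (uni > 0 && inter / uni > iou_thr) removed[j] = true;
    }
  }
  return wrap(keep);
}
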