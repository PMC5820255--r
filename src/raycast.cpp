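// Ray-triangle intersection (Moller-Trumbore) and all-hits raycast
// resampling of a triangle mesh along a fixed direction set.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// returns t >= 0 of the intersection, or NA when the ray misses
inline double mt_hit(const double* o, const double* d,
                     const double* v0, const double* v1, const double* v2) {
  const double EPS = 1e-12;
  double e1[3] = {v1[0] - v0[0], v1[1] - v0[1], v1[2] - v0[2]};
  double e2[3] = {v2[0] - v0[0], v2[1] - v0[1], v2[2] - v0[2]};
  double p[3] = {d[1] * e2[2] - d[2] * e2[1],
                 d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < EPS) return NA_REAL; // parallel or degenerate
  double inv = 1.0 / det;
  double s[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
  double u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (u < -1e-12 || u > 1 + 1e-12) return NA_REAL;
  double q[3] = {s[1] * e1[2] - s[2] * e1[1],
                 s[2] * e1[0] - s[0] * e1[2],
                 s[0] * e1[1] - s[1] * e1[0]};
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-12 || u + v > 1 + 1e-12) return NA_REAL;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  if (t < -1e-12) return NA_REAL;
  return t < 0 ? 0.0 : t;
}

} // namespace

// [[Rcpp::export(name = ".ray_triangle_cpp")]]
double ray_triangle_cpp(NumericVector origin, NumericVector direction,
                        NumericMatrix triangle) {
  double v0[3] = {triangle(0, 0), triangle(0, 1), triangle(0, 2)};
  double v1[3] = {triangle(1, 0), triangle(1, 1), triangle(1, 2)};
  double v2[3] = {triangle(2, 0), triangle(2, 1), triangle(2, 2)};
  return mt_hit(REAL(origin), REAL(direction), v0, v1, v2);
}

// [[Rcpp::export(name = ".raycast_all_cpp")]]
List raycast_all_cpp(NumericMatrix directions, NumericVector origin,
                     NumericMatrix V, IntegerMatrix F) {
  const int nd = directions.nrow();
  const int nf = F.nrow();
  NumericVector inner(nd, NA_REAL), outer(nd, NA_REAL);
  LogicalVector valid(nd, false);
  IntegerVector nhits(nd, 0);
  const double o[3] = {origin[0], origin[1], origin[2]};
  std::vector<double> ts;
  for (int r = 0; r < nd; ++r) {
    const double d[3] = {directions(r, 0), directions(r, 1), directions(r, 2)};
    ts.clear();
    for (int f = 0; f < nf; ++f) {
      const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      double v0[3] = {V(a, 0), V(a, 1), V(a, 2)};
      double v1[3] = {V(b, 0), V(b, 1), V(b, 2)};
      double v2[3] = {V(c, 0), V(c, 1), V(c, 2)};
      double t = mt_hit(o, d, v0, v1, v2);
      if (!ISNA(t)) ts.push_back(t);
    }
    if (ts.empty()) continue;
    std::sort(ts.begin(), ts.end());
    // collapse duplicate hits on shared edges/vertices
    int uniq = 1;
    for (size_t s = 1; s < ts.size(); ++s)
      if (ts[s] - ts[s - 1] >= 1e-9) ++uniq;
    inner[r] = ts.front();
    outer[r] = ts.back();
    valid[r] = true;
    nhits[r] = uniq;
  }
  return List::create(_["inner"] = inner, _["outer"] = outer,
                      _["valid"] = valid, _["n_hits"] = nhits);
}
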