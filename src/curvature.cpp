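// Per-vertex Gaussian curvature by area-weighted implicit quadric fitting.
//
// For each vertex the faces whose centroids lie within a metric radius are
// collected (restricted to the vertex's connected component); an implicit
// quadric F(x) = x'Ax + b'x + c is fitted by total least squares on the
// area-weighted monomial scatter (smallest eigenvector, unit-norm
// coefficients); Gaussian curvature follows the implicit-surface formula
//   kappa_G = grad(F) adj(H) grad(F)' / |grad(F)|^4 ,   H = 2A,
// and an orientation sign (+1 convex / -1 concave w.r.t. the outward
// normal) is taken from the sign of the implicit mean curvature.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// monomial row [x2 y2 z2 xy xz yz x y z 1]
inline void monomials(const double* p, double* m) {
  m[0] = p[0] * p[0]; m[1] = p[1] * p[1]; m[2] = p[2] * p[2];
  m[3] = p[0] * p[1]; m[4] = p[0] * p[2]; m[5] = p[1] * p[2];
  m[6] = p[0]; m[7] = p[1]; m[8] = p[2]; m[9] = 1.0;
}

// fit on local coordinates; returns 0 ok, 1 ambiguous
int fit_quadric_core(const arma::mat& P, const arma::vec& w, arma::vec& coef) {
  const int n = (int)P.n_rows;
  arma::mat M(10, 10, arma::fill::zeros);
  double row[10];
  for (int i = 0; i < n; ++i) {
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    monomials(p, row);
    const arma::vec m(row, 10);
    M += w(i) * (m * m.t());
  }
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, M)) return 1;
  const double lmax = eval(9) > 0 ? eval(9) : 1.0;
  const double tol = 1e-10 * lmax;
  int k = 0;
  while (k < 10 && eval(k) < tol) ++k;
  if (k <= 1) {
    coef = evec.col(0);
  } else {
    // degenerate null space (e.g. planar data): pick the representative
    // with the smallest quadratic part; ambiguous if that is non-unique
    arma::mat N = evec.cols(0, k - 1);
    arma::mat Q = N.rows(0, 5);
    arma::mat S = Q.t() * Q;
    arma::vec se;
    arma::mat sv;
    if (!arma::eig_sym(se, sv, S)) return 1;
    if (k >= 2 && se(1) < 1e-12 * std::max(1.0, se(k - 1))) return 1;
    coef = N * sv.col(0);
  }
  double nrm = arma::norm(coef);
  if (nrm < 1e-300) return 1;
  coef /= nrm;
  return 0;
}

// Goldman curvature + orientation sign from unit-norm coefficients,
// evaluated at the local origin with given outward normal.
// Returns false when the gradient vanishes.
bool curvature_from_coef(arma::vec coef, const double* nrm,
                         double& kappa, int& osign) {
  arma::mat33 A = {{coef(0), coef(3) / 2, coef(4) / 2},
                   {coef(3) / 2, coef(1), coef(5) / 2},
                   {coef(4) / 2, coef(5) / 2, coef(2)}};
  arma::vec3 g = {coef(6), coef(7), coef(8)};
  double gn = arma::norm(g);
  if (gn < 1e-9) return false;
  double dn = g(0) * nrm[0] + g(1) * nrm[1] + g(2) * nrm[2];
  if (dn < 0) { A = -A; g = -g; } // align gradient with the outward normal
  arma::mat33 H = 2.0 * A;
  // adjugate of the symmetric 3x3 Hessian
  arma::mat33 adj;
  adj(0, 0) = H(1, 1) * H(2, 2) - H(1, 2) * H(2, 1);
  adj(0, 1) = H(0, 2) * H(2, 1) - H(0, 1) * H(2, 2);
  adj(0, 2) = H(0, 1) * H(1, 2) - H(0, 2) * H(1, 1);
  adj(1, 0) = adj(0, 1);
  adj(1, 1) = H(0, 0) * H(2, 2) - H(0, 2) * H(2, 0);
  adj(1, 2) = H(0, 2) * H(1, 0) - H(0, 0) * H(1, 2);
  adj(2, 0) = adj(0, 2);
  adj(2, 1) = adj(1, 2);
  adj(2, 2) = H(0, 0) * H(1, 1) - H(0, 1) * H(1, 0);
  double g2 = gn * gn;
  kappa = arma::as_scalar(g.t() * adj * g) / (g2 * g2);
  // implicit mean curvature numerator: negative => bends away from the
  // outward-aligned gradient => convex
  double num = arma::as_scalar(g.t() * H * g) - g2 * arma::trace(H);
  osign = (num <= 0) ? 1 : -1;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".fit_quadric_cpp")]]
List fit_quadric_cpp(NumericMatrix centroids, NumericVector areas) {
  arma::mat P(centroids.begin(), centroids.nrow(), 3, false);
  arma::vec w(areas.begin(), areas.size(), false);
  arma::vec coef;
  int status = fit_quadric_core(P, w, coef);
  if (status != 0)
    return List::create(_["ok"] = false);
  return List::create(_["ok"] = true,
                      _["coef"] = NumericVector(coef.begin(), coef.end()));
}

// [[Rcpp::export(name = ".curvature_all_cpp")]]
List curvature_all_cpp(NumericMatrix Vm, IntegerMatrix Fm,
                       IntegerVector comp, NumericMatrix normals,
                       double radius, int min_faces) {
  const int nv = Vm.nrow(), nf = Fm.nrow();
  // face centroids, areas, component label (from first corner)
  std::vector<double> cx(nf), cy(nf), cz(nf), fa(nf);
  std::vector<int> fcomp(nf);
  for (int f = 0; f < nf; ++f) {
    const int a = Fm(f, 0) - 1, b = Fm(f, 1) - 1, c = Fm(f, 2) - 1;
    cx[f] = (Vm(a, 0) + Vm(b, 0) + Vm(c, 0)) / 3.0;
    cy[f] = (Vm(a, 1) + Vm(b, 1) + Vm(c, 1)) / 3.0;
    cz[f] = (Vm(a, 2) + Vm(b, 2) + Vm(c, 2)) / 3.0;
    double u[3] = {Vm(b, 0) - Vm(a, 0), Vm(b, 1) - Vm(a, 1), Vm(b, 2) - Vm(a, 2)};
    double v[3] = {Vm(c, 0) - Vm(a, 0), Vm(c, 1) - Vm(a, 1), Vm(c, 2) - Vm(a, 2)};
    double n0 = u[1] * v[2] - u[2] * v[1];
    double n1 = u[2] * v[0] - u[0] * v[2];
    double n2 = u[0] * v[1] - u[1] * v[0];
    fa[f] = 0.5 * std::sqrt(n0 * n0 + n1 * n1 + n2 * n2);
    fcomp[f] = comp[a];
  }
  // uniform-grid binning of face centroids (cell size = patch radius)
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int f = 0; f < nf; ++f) {
    lo[0] = std::min(lo[0], cx[f]); hi[0] = std::max(hi[0], cx[f]);
    lo[1] = std::min(lo[1], cy[f]); hi[1] = std::max(hi[1], cy[f]);
    lo[2] = std::min(lo[2], cz[f]); hi[2] = std::max(hi[2], cz[f]);
  }
  const double cell = radius;
  int gb[3];
  for (int d = 0; d < 3; ++d)
    gb[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  auto cell_of = [&](double x, double y, double z) {
    int ix = std::min(gb[0] - 1, std::max(0, (int)((x - lo[0]) / cell)));
    int iy = std::min(gb[1] - 1, std::max(0, (int)((y - lo[1]) / cell)));
    int iz = std::min(gb[2] - 1, std::max(0, (int)((z - lo[2]) / cell)));
    return ix + gb[0] * (iy + gb[1] * iz);
  };
  std::vector<std::vector<int>> bins((size_t)gb[0] * gb[1] * gb[2]);
  for (int f = 0; f < nf; ++f) bins[cell_of(cx[f], cy[f], cz[f])].push_back(f);

  NumericVector kappa(nv, NA_REAL);
  IntegerVector osign(nv, NA_INTEGER);
  LogicalVector supported(nv, false);
  const double r2 = radius * radius;
  std::vector<int> patch;
  for (int v = 0; v < nv; ++v) {
    const double px = Vm(v, 0), py = Vm(v, 1), pz = Vm(v, 2);
    const int vc = comp[v];
    patch.clear();
    int bx = std::min(gb[0] - 1, std::max(0, (int)((px - lo[0]) / cell)));
    int by = std::min(gb[1] - 1, std::max(0, (int)((py - lo[1]) / cell)));
    int bz = std::min(gb[2] - 1, std::max(0, (int)((pz - lo[2]) / cell)));
    for (int iz = std::max(0, bz - 1); iz <= std::min(gb[2] - 1, bz + 1); ++iz)
      for (int iy = std::max(0, by - 1); iy <= std::min(gb[1] - 1, by + 1); ++iy)
        for (int ix = std::max(0, bx - 1); ix <= std::min(gb[0] - 1, bx + 1); ++ix)
          for (int f : bins[(size_t)ix + gb[0] * ((size_t)iy + gb[1] * iz)]) {
            if (fcomp[f] != vc) continue;
            const double dx = cx[f] - px, dy = cy[f] - py, dz = cz[f] - pz;
            if (dx * dx + dy * dy + dz * dz <= r2) patch.push_back(f);
          }
    if ((int)patch.size() < min_faces) continue;
    arma::mat P(patch.size(), 3);
    arma::vec w(patch.size());
    for (size_t s = 0; s < patch.size(); ++s) {
      const int f = patch[s];
      P(s, 0) = cx[f] - px; P(s, 1) = cy[f] - py; P(s, 2) = cz[f] - pz;
      w(s) = fa[f];
    }
    arma::vec coef;
    if (fit_quadric_core(P, w, coef) != 0) continue;
    const double n[3] = {normals(v, 0), normals(v, 1), normals(v, 2)};
    double kg;
    int sg;
    if (!curvature_from_coef(coef, n, kg, sg)) continue;
    kappa[v] = kg;
    osign[v] = sg;
    supported[v] = true;
  }
  return List::create(_["kappa_g"] = kappa, _["orientation_sign"] = osign,
                      _["supported"] = supported);
}
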