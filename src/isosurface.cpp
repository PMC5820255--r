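// Iso-surface extraction on a regular 3D grid by marching tetrahedra.
// Each grid cell is split into 6 tetrahedra around the 0-6 body diagonal;
// the iso-surface of the per-tet linear interpolant is triangulated with
// vertices welded on shared grid edges, so the output is watertight and
// consistently oriented (normals point towards increasing field values).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Welder {
  std::unordered_map<uint64_t, int> seen;
  std::vector<double> vx, vy, vz;
  // interpolated point on grid edge (a,b); ga/gb are global grid ids
  int vertex(uint64_t ga, uint64_t gb, const double* pa, const double* pb,
             double fa, double fb, double level) {
    uint64_t key = ga < gb ? (ga << 32) | gb : (gb << 32) | ga;
    // grid vertex ids are far below 2^32; key is collision-free
    auto it = seen.find(key);
    if (it != seen.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    seen.emplace(key, id);
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx < 2 || ny < 2 || nz < 2)
    stop("grid must be at least 2 on every axis");
  const double* f0 = REAL(field);
  // nudge values equal to the level so every crossing is strict
  std::vector<double> f(f0, f0 + (size_t)nx * ny * nz);
  const double eps = 1e-12;
  for (auto& v : f) if (v == level) v = level + eps;

  // 6 tetrahedra spanning the 0-6 diagonal of the unit cube
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};

  Welder w;
  std::vector<int> tri;

  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };

  double P[8][3];
  double F[8];
  uint64_t G[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool lo = false, hi = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner[c][0], cj = j + corner[c][1], ck = k + corner[c][2];
          G[c] = gid(ci, cj, ck);
          F[c] = f[G[c]];
          P[c][0] = ci; P[c][1] = cj; P[c][2] = ck;
          (F[c] < level ? lo : hi) = true;
        }
        if (!lo || !hi) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int in[4], out[4], ni = 0, no = 0;
          for (int s = 0; s < 4; ++s)
            (F[tv[s]] < level ? in[ni++] : out[no++]) = tv[s];
          if (ni == 0 || ni == 4) continue;
          auto ev = [&](int a, int b) {
            return w.vertex(G[a], G[b], P[a], P[b], F[a], F[b], level);
          };
          int ids[4], n = 0;
          if (ni == 1) {
            ids[0] = ev(in[0], out[0]);
            ids[1] = ev(in[0], out[1]);
            ids[2] = ev(in[0], out[2]);
            n = 3;
          } else if (ni == 3) {
            ids[0] = ev(in[0], out[0]);
            ids[1] = ev(in[1], out[0]);
            ids[2] = ev(in[2], out[0]);
            n = 3;
          } else { // 2 in, 2 out: a quad
            ids[0] = ev(in[0], out[0]);
            ids[1] = ev(in[0], out[1]);
            ids[2] = ev(in[1], out[1]);
            ids[3] = ev(in[1], out[0]);
            n = 4;
          }
          // orient each emitted triangle so its normal points to the
          // outside (field > level) half-space of the linear interpolant
          const double* po = P[out[0]];
          auto emit = [&](int a, int b, int c) {
            double ax = w.vx[a], ay = w.vy[a], az = w.vz[a];
            double ux = w.vx[b] - ax, uy = w.vy[b] - ay, uz = w.vz[b] - az;
            double vx2 = w.vx[c] - ax, vy2 = w.vy[c] - ay, vz2 = w.vz[c] - az;
            double nxc = uy * vz2 - uz * vy2;
            double nyc = uz * vx2 - ux * vz2;
            double nzc = ux * vy2 - uy * vx2;
            double d = nxc * (po[0] - ax) + nyc * (po[1] - ay) + nzc * (po[2] - az);
            if (d >= 0) { tri.push_back(a); tri.push_back(b); tri.push_back(c); }
            else        { tri.push_back(a); tri.push_back(c); tri.push_back(b); }
          };
          if (n == 3) emit(ids[0], ids[1], ids[2]);
          else { emit(ids[0], ids[1], ids[2]); emit(ids[0], ids[2], ids[3]); }
        }
      }

  const int nv = (int)w.vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = w.vx[v]; V(v, 1) = w.vy[v]; V(v, 2) = w.vz[v];
  }
  const int nf = (int)tri.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int r = 0; r < nf; ++r) {
    Fm(r, 0) = tri[3 * r] + 1;      // 1-based for R
    Fm(r, 1) = tri[3 * r + 1] + 1;
    Fm(r, 2) = tri[3 * r + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims) {
  // 6-connected component labelling of a 3D logical grid (BFS flood fill)
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int* m = LOGICAL(mask);
  std::vector<size_t> queue;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      size_t cur = queue.back();
      queue.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((size_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t q = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (m[q] && lab[q] == 0) { lab[q] = next; queue.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
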