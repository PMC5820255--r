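// Breadth-first ring neighbourhoods on the mesh vertex graph and
// ring-wise curvature-map assembly for all vertices at once.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// BFS graph distances from v0, capped at max_depth; -1 beyond the cap.
// adj is CSR with 0-based indices; ptr has length n+1.
void bfs_rings(const int* ptr, const int* idx, int n, int v0, int max_depth,
               std::vector<int>& dist, std::vector<int>& order) {
  dist.assign(n, -1);
  order.clear();
  dist[v0] = 0;
  order.push_back(v0);
  size_t head = 0;
  while (head < order.size()) {
    int u = order[head++];
    if (dist[u] == max_depth) continue;
    for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
      int w = idx[e];
      if (dist[w] < 0) { dist[w] = dist[u] + 1; order.push_back(w); }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".ring_distances_cpp")]]
IntegerVector ring_distances_cpp(IntegerVector ptr, IntegerVector idx,
                                 int v0, int max_depth) {
  const int n = ptr.size() - 1;
  std::vector<int> dist, order;
  bfs_rings(INTEGER(ptr), INTEGER(idx), n, v0, max_depth, dist, order);
  return IntegerVector(dist.begin(), dist.end());
}

// [[Rcpp::export(name = ".ring_maps_all_cpp")]]
List ring_maps_all_cpp(IntegerVector ptr, IntegerVector idx,
                       NumericVector weight, NumericVector kappa,
                       IntegerVector osign, LogicalVector boundary,
                       IntegerVector centres, int n_rings,
                       double kappa_floor) {
  const int n = ptr.size() - 1;
  const int nc = centres.size();
  const int ncol = n_rings + 1;
  NumericMatrix entries(nc, ncol);
  IntegerMatrix partial(nc, ncol);
  std::vector<int> dist, order;
  std::vector<double> sw(ncol), sk(ncol), ss(ncol);
  std::vector<int> pb(ncol);
  for (int ci = 0; ci < nc; ++ci) {
    const int v0 = centres[ci];
    bfs_rings(INTEGER(ptr), INTEGER(idx), n, v0, n_rings, dist, order);
    std::fill(sw.begin(), sw.end(), 0.0);
    std::fill(sk.begin(), sk.end(), 0.0);
    std::fill(ss.begin(), ss.end(), 0.0);
    std::fill(pb.begin(), pb.end(), 0);
    for (int u : order) {
      const int r = dist[u];
      sw[r] += weight[u];
      sk[r] += weight[u] * kappa[u];
      ss[r] += weight[u] * osign[u];
      if (boundary[u]) pb[r] = 1;
    }
    for (int r = 0; r < ncol; ++r) {
      if (sw[r] <= 0) {
        entries(ci, r) = 0.0;
        partial(ci, r) = 1;
        continue;
      }
      const double kbar = sk[r] / sw[r];
      const int sg = (ss[r] >= 0) ? 1 : -1;
      const double mag = std::max(std::fabs(kbar), kappa_floor);
      const double Rs = 1.0 / std::sqrt(mag);
      entries(ci, r) = sg * std::log1p(Rs);
      partial(ci, r) = pb[r];
    }
  }
  return List::create(_["entries"] = entries, _["partial"] = partial);
}
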