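#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling (6- or 26-connectivity), BFS flood fill.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long sy = nz, sx = (long)nz * ny;
  const long n = (long)nz * ny * nx;
  IntegerVector lab(n); // zero-initialized
  std::vector<int> offk, offj, offi;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        const int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        offk.push_back(dk); offj.push_back(dj); offi.push_back(di);
      }
  const int nb = (int)offk.size();
  int next = 0;
  std::queue<long> q;
  for (long t = 0; t < n; ++t) {
    if (!mask[t] || lab[t] != 0) continue;
    ++next;
    lab[t] = next;
    q.push(t);
    while (!q.empty()) {
      const long cur = q.front(); q.pop();
      const int i = (int)(cur / sx);
      const int j = (int)((cur - (long)i * sx) / sy);
      const int k = (int)(cur - (long)i * sx - (long)j * sy);
      for (int b = 0; b < nb; ++b) {
        const int kk = k + offk[b], jj = j + offj[b], ii = i + offi[b];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx) continue;
        const long t2 = kk + sy * jj + sx * ii;
        if (mask[t2] && lab[t2] == 0) { lab[t2] = next; q.push(t2); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Geodesic distance within `domain` from `seeds` (multi-source Dijkstra,
// 26-neighborhood, steps weighted by physical length in nm). Voxels outside
// the domain or unreachable get +Inf.
// [[Rcpp::export]]
NumericVector cpp_geodesic3d(LogicalVector domain, LogicalVector seeds,
                             IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long sy = nz, sx = (long)nz * ny;
  const long n = (long)nz * ny * nx;
  NumericVector dist(n, R_PosInf);
  std::vector<int> offk, offj, offi;
  std::vector<double> w;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        offk.push_back(dk); offj.push_back(dj); offi.push_back(di);
        const double dz = dk * spacing[0], dy = dj * spacing[1], dx = di * spacing[2];
        w.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
      }
  const int nb = (int)offk.size();
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (long t = 0; t < n; ++t)
    if (seeds[t] && domain[t]) { dist[t] = 0.0; pq.push(Node(0.0, t)); }
  while (!pq.empty()) {
    const Node nd = pq.top(); pq.pop();
    const double dcur = nd.first;
    const long cur = nd.second;
    if (dcur > dist[cur]) continue;
    const int i = (int)(cur / sx);
    const int j = (int)((cur - (long)i * sx) / sy);
    const int k = (int)(cur - (long)i * sx - (long)j * sy);
    for (int b = 0; b < nb; ++b) {
      const int kk = k + offk[b], jj = j + offj[b], ii = i + offi[b];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx) continue;
      const long t2 = kk + sy * jj + sx * ii;
      if (!domain[t2]) continue;
      const double nd2 = dcur + w[b];
      if (nd2 < dist[t2]) { dist[t2] = nd2; pq.push(Node(nd2, t2)); }
    }
  }
  dist.attr("dim") = dim;
  return dist;
}
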