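#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3D medial-axis thinning: iterative removal of simple border points with
// curve-endpoint preservation, in six directional sub-iterations (candidates
// are re-checked sequentially before deletion so connectivity is preserved).
// A voxel is simple when (a) its 26-neighborhood foreground forms exactly one
// 26-connected component and (b) the background within its 18-neighborhood
// forms exactly one 6-connected component that touches a face neighbor
// (Bertrand & Malandain characterization).

namespace {

struct Grid {
  const std::vector<unsigned char>* img;
  int nz, ny, nx;
  long sy, sx;
  inline bool fg(int k, int j, int i) const {
    if (k < 0 || k >= nz || j < 0 || j >= ny || i < 0 || i >= nx) return false;
    return (*img)[k + sy * j + sx * i] != 0;
  }
};

// neighborhood index helpers: 3x3x3 cube, local coords in {-1,0,1}
inline int lidx(int dk, int dj, int di) { return (dk + 1) + 3 * (dj + 1) + 9 * (di + 1); }

bool is_simple(const Grid& g, int k, int j, int i) {
  bool nb[27];
  int nfg = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        const int t = lidx(dk, dj, di);
        if (dk == 0 && dj == 0 && di == 0) { nb[t] = false; continue; }
        nb[t] = g.fg(k + dk, j + dj, i + di);
        if (nb[t]) ++nfg;
      }
  if (nfg == 0) return false; // isolated point: keep

  // (a) one 26-connected foreground component among the 26 neighbors
  int comp = 0;
  bool seen[27];
  std::memset(seen, 0, sizeof(seen));
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!nb[s] || seen[s]) continue;
    if (++comp > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      const int cur = stack[--top];
      const int ck = cur % 3 - 1, cj = (cur / 3) % 3 - 1, ci = cur / 9 - 1;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk) {
            const int ek = ck + dk, ej = cj + dj, ei = ci + di;
            if (ek < -1 || ek > 1 || ej < -1 || ej > 1 || ei < -1 || ei > 1) continue;
            const int t = lidx(ek, ej, ei);
            if (nb[t] && !seen[t]) { seen[t] = true; stack[top++] = t; }
          }
    }
  }
  if (comp != 1) return false;

  // (b) background 6-connectivity within the 18-neighborhood, seeded at face
  // neighbors; exactly one such component
  bool bg18[27];
  std::memset(bg18, 0, sizeof(bg18));
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        const int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (man == 0 || man == 3) continue; // 18-neighborhood only
        const int t = lidx(dk, dj, di);
        bg18[t] = !nb[t];
      }
  const int faces[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
  std::memset(seen, 0, sizeof(seen));
  comp = 0;
  for (int fcase = 0; fcase < 6; ++fcase) {
    const int t0 = lidx(faces[fcase][0], faces[fcase][1], faces[fcase][2]);
    if (!bg18[t0] || seen[t0]) continue;
    if (++comp > 1) return false;
    int top = 0;
    int stack2[27];
    stack2[top++] = t0;
    seen[t0] = true;
    while (top > 0) {
      const int cur = stack2[--top];
      const int ck = cur % 3 - 1, cj = (cur / 3) % 3 - 1, ci = cur / 9 - 1;
      const int step[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
      for (int s = 0; s < 6; ++s) {
        const int ek = ck + step[s][0], ej = cj + step[s][1], ei = ci + step[s][2];
        if (ek < -1 || ek > 1 || ej < -1 || ej > 1 || ei < -1 || ei > 1) continue;
        const int t = lidx(ek, ej, ei);
        if (bg18[t] && !seen[t]) { seen[t] = true; stack2[top++] = t; }
      }
    }
  }
  return comp == 1;
}

int count_fg_neighbors(const Grid& g, int k, int j, int i) {
  int c = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (dk == 0 && dj == 0 && di == 0) continue;
        if (g.fg(k + dk, j + dj, i + di)) ++c;
      }
  return c;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long sy = nz, sx = (long)nz * ny;
  const long n = (long)nz * ny * nx;
  std::vector<unsigned char> img(n);
  for (long t = 0; t < n; ++t) img[t] = mask[t] ? 1 : 0;
  Grid g;
  g.img = &img; g.nz = nz; g.ny = ny; g.nx = nx; g.sy = sy; g.sx = sx;

  const int dirs[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
  bool changed = true;
  std::vector<long> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int i = 0; i < nx; ++i)
        for (int j = 0; j < ny; ++j)
          for (int k = 0; k < nz; ++k) {
            const long t = k + sy * j + sx * i;
            if (!img[t]) continue;
            // border point in direction d (face neighbor is background)
            if (g.fg(k + dirs[d][0], j + dirs[d][1], i + dirs[d][2])) continue;
            if (count_fg_neighbors(g, k, j, i) <= 1) continue; // endpoint
            if (is_simple(g, k, j, i)) cand.push_back(t);
          }
      // sequential re-check before deleting
      for (size_t c = 0; c < cand.size(); ++c) {
        const long t = cand[c];
        const int i = (int)(t / sx);
        const int j = (int)((t - (long)i * sx) / sy);
        const int k = (int)(t - (long)i * sx - (long)j * sy);
        if (count_fg_neighbors(g, k, j, i) <= 1) continue;
        if (is_simple(g, k, j, i)) { img[t] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (long t = 0; t < n; ++t) out[t] = img[t] != 0;
  out.attr("dim") = dim;
  return out;
}
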