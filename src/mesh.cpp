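#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction from a scalar voxel grid. Each grid cell (8 voxel
// centers) is split into the six Freudenthal tetrahedra sharing the main
// diagonal, and each tetrahedron is triangulated by linear interpolation
// along its edges at the isovalue crossing. The decomposition is consistent
// across shared cell faces, so closed level sets yield watertight meshes.
// "Inside" means value > isovalue. For binary data meshed at the mid-level
// isovalue, crossings land at the exact midpoints between voxel centers.

namespace {

struct V3 { double x, y, z; };

inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
inline V3 sub(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 add(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 scale(const V3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const V3& a) { return dot(a, a); }

struct MeshBuilder {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // flat, 0-based

  int edge_point(long g1, long g2, const V3& p1, const V3& p2,
                 double f1, double f2, double iso) {
    uint64_t a = (uint64_t)std::min(g1, g2), b = (uint64_t)std::max(g1, g2);
    uint64_t key = (a << 32) | b;
    std::unordered_map<uint64_t, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (f2 != f1) ? (iso - f1) / (f2 - f1) : 0.5;
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    V3 p = add(p1, scale(sub(p2, p1), t));
    int id = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    edge_vertex[key] = id;
    return id;
  }

  // append triangle (i1,i2,i3) oriented so its normal has positive dot with ref
  void add_tri(int i1, int i2, int i3, const V3& ref_dir, const V3& ref_origin) {
    V3 a = v3(vx[i1], vy[i1], vz[i1]);
    V3 b = v3(vx[i2], vy[i2], vz[i2]);
    V3 c = v3(vx[i3], vy[i3], vz[i3]);
    V3 n = cross(sub(b, a), sub(c, a));
    if (dot(n, sub(ref_dir, ref_origin)) < 0) std::swap(i2, i3);
    tri.push_back(i1); tri.push_back(i2); tri.push_back(i3);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_isosurface(NumericVector arr, IntegerVector dim, double iso,
                    NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long sy = nz, sx = (long)nz * ny;
  const double c = spacing[0], b = spacing[1], a = spacing[2];

  // cube corners indexed by (dx, dy, dz) bit layout of the usual MC order
  const int cx[8] = { 0, 1, 1, 0, 0, 1, 1, 0 };
  const int cy[8] = { 0, 0, 1, 1, 0, 0, 1, 1 };
  const int cz[8] = { 0, 0, 0, 0, 1, 1, 1, 1 };
  // six tetrahedra sharing the main diagonal corner0 - corner6
  const int tets[6][4] = {
    { 0, 1, 2, 6 }, { 0, 2, 3, 6 }, { 0, 3, 7, 6 },
    { 0, 7, 4, 6 }, { 0, 4, 5, 6 }, { 0, 5, 1, 6 }
  };

  MeshBuilder mb;
  double fv[8];
  long gid[8];
  V3 pos[8];

  for (int i = 0; i + 1 < nx; ++i)
    for (int j = 0; j + 1 < ny; ++j)
      for (int k = 0; k + 1 < nz; ++k) {
        bool any_in = false, any_out = false;
        for (int t = 0; t < 8; ++t) {
          const int ii = i + cx[t], jj = j + cy[t], kk = k + cz[t];
          const long g = kk + sy * jj + sx * ii;
          gid[t] = g;
          fv[t] = arr[g];
          pos[t] = v3(ii * a, jj * b, kk * c);
          if (fv[t] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in_ids[4], out_ids[4];
          int nin = 0, nout = 0;
          for (int s = 0; s < 4; ++s) {
            const int cidx = tets[t][s];
            if (fv[cidx] > iso) in_ids[nin++] = cidx; else out_ids[nout++] = cidx;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            const int A = (nin == 1) ? in_ids[0] : out_ids[0];
            const int* others = (nin == 1) ? out_ids : in_ids;
            int e[3];
            for (int s = 0; s < 3; ++s)
              e[s] = mb.edge_point(gid[A], gid[others[s]], pos[A], pos[others[s]],
                                   fv[A], fv[others[s]], iso);
            // outward = away from the inside region
            V3 ref_origin, ref_dir;
            V3 cen = scale(add(add(v3(mb.vx[e[0]], mb.vy[e[0]], mb.vz[e[0]]),
                                   v3(mb.vx[e[1]], mb.vy[e[1]], mb.vz[e[1]])),
                               v3(mb.vx[e[2]], mb.vy[e[2]], mb.vz[e[2]])), 1.0 / 3.0);
            if (nin == 1) { ref_origin = pos[A]; ref_dir = cen; } // away from inside corner A
            else { ref_origin = cen; ref_dir = pos[A]; }          // toward outside corner A
            mb.add_tri(e[0], e[1], e[2], ref_dir, ref_origin);
          } else { // 2 in, 2 out -> quad
            const int A = in_ids[0], B = in_ids[1], C = out_ids[0], D = out_ids[1];
            const int eAC = mb.edge_point(gid[A], gid[C], pos[A], pos[C], fv[A], fv[C], iso);
            const int eAD = mb.edge_point(gid[A], gid[D], pos[A], pos[D], fv[A], fv[D], iso);
            const int eBC = mb.edge_point(gid[B], gid[C], pos[B], pos[C], fv[B], fv[C], iso);
            const int eBD = mb.edge_point(gid[B], gid[D], pos[B], pos[D], fv[B], fv[D], iso);
            V3 min_ = scale(add(pos[A], pos[B]), 0.5);
            V3 mout = scale(add(pos[C], pos[D]), 0.5);
            mb.add_tri(eAC, eAD, eBD, mout, min_);
            mb.add_tri(eAC, eBD, eBC, mout, min_);
          }
        }
      }

  // weld coincident vertices (1e-6 nm quantization) and drop degenerate tris
  const double q = 1e6;
  std::unordered_map<uint64_t, int> weld;
  std::vector<int> remap(mb.vx.size());
  std::vector<double> wx, wy, wz;
  for (size_t vi = 0; vi < mb.vx.size(); ++vi) {
    const int64_t ix = (int64_t)std::llround(mb.vx[vi] * q);
    const int64_t iy = (int64_t)std::llround(mb.vy[vi] * q);
    const int64_t iz = (int64_t)std::llround(mb.vz[vi] * q);
    uint64_t h = (uint64_t)ix * 73856093ULL ^ (uint64_t)iy * 19349663ULL ^ (uint64_t)iz * 83492791ULL;
    std::unordered_map<uint64_t, int>::iterator it = weld.find(h);
    bool found = false;
    if (it != weld.end()) {
      const int w = it->second;
      if (std::llround(wx[w] * q) == ix && std::llround(wy[w] * q) == iy &&
          std::llround(wz[w] * q) == iz) { remap[vi] = w; found = true; }
    }
    if (!found) {
      const int w = (int)wx.size();
      wx.push_back(mb.vx[vi]); wy.push_back(mb.vy[vi]); wz.push_back(mb.vz[vi]);
      weld[h] = w;
      remap[vi] = w;
    }
  }
  std::vector<int> tris;
  tris.reserve(mb.tri.size());
  for (size_t t = 0; t < mb.tri.size(); t += 3) {
    const int i1 = remap[mb.tri[t]], i2 = remap[mb.tri[t + 1]], i3 = remap[mb.tri[t + 2]];
    if (i1 == i2 || i2 == i3 || i1 == i3) continue;
    const V3 p1 = v3(wx[i1], wy[i1], wz[i1]);
    const V3 p2 = v3(wx[i2], wy[i2], wz[i2]);
    const V3 p3 = v3(wx[i3], wy[i3], wz[i3]);
    if (norm2(cross(sub(p2, p1), sub(p3, p1))) < 1e-24) continue;
    tris.push_back(i1); tris.push_back(i2); tris.push_back(i3);
  }

  const int nv = (int)wx.size();
  const int nt = (int)tris.size() / 3;
  NumericMatrix V(nv, 3);
  for (int vi = 0; vi < nv; ++vi) { V(vi, 0) = wx[vi]; V(vi, 1) = wy[vi]; V(vi, 2) = wz[vi]; }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tris[3 * t] + 1; T(t, 1) = tris[3 * t + 1] + 1; T(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("triangles") = T);
}

// ---------------------------------------------------------------------------
// point-to-mesh distance

namespace {

// Ericson's closest point on triangle
V3 closest_point_triangle(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return add(a, scale(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return add(a, scale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scale(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scale(ab, v), scale(ac, w)));
}

} // namespace

namespace {

// AABB tree over triangles, longest-axis median split
struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children, or -1 at a leaf
  int begin, end;    // triangle index range at a leaf
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order; // triangle ids, permuted by the build

  double box_dist2(const BVHNode& n, const V3& q) const {
    double d2 = 0;
    const double qc[3] = { q.x, q.y, q.z };
    for (int a = 0; a < 3; ++a) {
      double d = std::max(0.0, std::max(n.lo[a] - qc[a], qc[a] - n.hi[a]));
      d2 += d * d;
    }
    return d2;
  }
};

int bvh_build(BVH& bvh, std::vector<double>& cx, std::vector<double>& cy,
              std::vector<double>& cz, const std::vector<V3>& A,
              const std::vector<V3>& B, const std::vector<V3>& C,
              int begin, int end) {
  BVHNode node;
  for (int a = 0; a < 3; ++a) { node.lo[a] = R_PosInf; node.hi[a] = R_NegInf; }
  for (int i = begin; i < end; ++i) {
    const int t = bvh.order[i];
    const double tl[3] = { std::min(A[t].x, std::min(B[t].x, C[t].x)),
                           std::min(A[t].y, std::min(B[t].y, C[t].y)),
                           std::min(A[t].z, std::min(B[t].z, C[t].z)) };
    const double th[3] = { std::max(A[t].x, std::max(B[t].x, C[t].x)),
                           std::max(A[t].y, std::max(B[t].y, C[t].y)),
                           std::max(A[t].z, std::max(B[t].z, C[t].z)) };
    for (int a = 0; a < 3; ++a) {
      node.lo[a] = std::min(node.lo[a], tl[a]);
      node.hi[a] = std::max(node.hi[a], th[a]);
    }
  }
  const int id = (int)bvh.nodes.size();
  bvh.nodes.push_back(node);
  if (end - begin <= 8) {
    bvh.nodes[id].left = bvh.nodes[id].right = -1;
    bvh.nodes[id].begin = begin;
    bvh.nodes[id].end = end;
    return id;
  }
  int axis = 0;
  double ext = node.hi[0] - node.lo[0];
  for (int a = 1; a < 3; ++a)
    if (node.hi[a] - node.lo[a] > ext) { ext = node.hi[a] - node.lo[a]; axis = a; }
  const int mid = (begin + end) / 2;
  const std::vector<double>& key = (axis == 0) ? cx : (axis == 1) ? cy : cz;
  std::nth_element(bvh.order.begin() + begin, bvh.order.begin() + mid,
                   bvh.order.begin() + end,
                   [&key](int a, int b) { return key[a] < key[b]; });
  const int l = bvh_build(bvh, cx, cy, cz, A, B, C, begin, mid);
  const int r = bvh_build(bvh, cx, cy, cz, A, B, C, mid, end);
  bvh.nodes[id].left = l;
  bvh.nodes[id].right = r;
  bvh.nodes[id].begin = bvh.nodes[id].end = -1;
  return id;
}

} // namespace

// For each query point, the distance to the nearest point on any reference
// triangle, with the index of that triangle and the sign of the offset along
// the triangle normal (positive = on the outward side for outward-oriented
// meshes). AABB-tree acceleration; exact result.
// [[Rcpp::export]]
List cpp_mesh_distance(NumericMatrix query, NumericMatrix verts,
                       IntegerMatrix tris) {
  const int np = query.nrow(), nt = tris.nrow();
  std::vector<V3> A(nt), B(nt), C(nt);
  std::vector<double> cx(nt), cy(nt), cz(nt);
  for (int t = 0; t < nt; ++t) {
    A[t] = v3(verts(tris(t, 0) - 1, 0), verts(tris(t, 0) - 1, 1), verts(tris(t, 0) - 1, 2));
    B[t] = v3(verts(tris(t, 1) - 1, 0), verts(tris(t, 1) - 1, 1), verts(tris(t, 1) - 1, 2));
    C[t] = v3(verts(tris(t, 2) - 1, 0), verts(tris(t, 2) - 1, 1), verts(tris(t, 2) - 1, 2));
    cx[t] = (A[t].x + B[t].x + C[t].x) / 3.0;
    cy[t] = (A[t].y + B[t].y + C[t].y) / 3.0;
    cz[t] = (A[t].z + B[t].z + C[t].z) / 3.0;
  }
  BVH bvh;
  bvh.order.resize(nt);
  for (int t = 0; t < nt; ++t) bvh.order[t] = t;
  bvh.nodes.reserve(2 * nt / 8 + 4);
  bvh_build(bvh, cx, cy, cz, A, B, C, 0, nt);

  NumericVector dist(np);
  IntegerVector nearest(np);
  IntegerVector side(np);
  std::vector<int> stack;
  stack.reserve(128);
  for (int p = 0; p < np; ++p) {
    const V3 q = v3(query(p, 0), query(p, 1), query(p, 2));
    double best = R_PosInf;
    int best_t = -1;
    V3 best_cp = q;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      const int ni = stack.back();
      stack.pop_back();
      const BVHNode& n = bvh.nodes[ni];
      if (bvh.box_dist2(n, q) >= best) continue;
      if (n.left < 0) {
        for (int i = n.begin; i < n.end; ++i) {
          const int t = bvh.order[i];
          const V3 cp = closest_point_triangle(q, A[t], B[t], C[t]);
          const double d2 = norm2(sub(q, cp));
          if (d2 < best) { best = d2; best_t = t; best_cp = cp; }
        }
      } else {
        const double dl = bvh.box_dist2(bvh.nodes[n.left], q);
        const double dr = bvh.box_dist2(bvh.nodes[n.right], q);
        // push the farther child first so the nearer is explored first
        if (dl <= dr) { stack.push_back(n.right); stack.push_back(n.left); }
        else { stack.push_back(n.left); stack.push_back(n.right); }
      }
    }
    dist[p] = std::sqrt(best);
    nearest[p] = best_t + 1;
    const V3 nrm = cross(sub(B[best_t], A[best_t]), sub(C[best_t], A[best_t]));
    side[p] = (dot(nrm, sub(q, best_cp)) >= 0) ? 1 : -1;
  }
  return List::create(Named("distance") = dist, Named("triangle") = nearest,
                      Named("side") = side);
}
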