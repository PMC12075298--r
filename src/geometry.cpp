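#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

// Grids are column-major with x fastest: flat = i + nx*(j + ny*k).
// World coordinate of voxel (i,j,k) center = origin + (i,j,k)*spacing.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 sub(const Vec3& a, const Vec3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 add(const Vec3& a, const Vec3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 scale(const Vec3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// z of intersection of vertical ray at (x, y) with triangle; returns true on hit.
// Half-open barycentric rule with a tiny jitter applied by the caller keeps
// shared edges from double-counting in practice.
inline bool ray_z_hit(double x, double y, const Vec3& a, const Vec3& b, const Vec3& c,
                      double& zhit) {
  const double d = (b.y - c.y) * (a.x - c.x) + (c.x - b.x) * (a.y - c.y);
  if (std::fabs(d) < 1e-300) return false;  // triangle vertical in z: no area in xy
  const double l1 = ((b.y - c.y) * (x - c.x) + (c.x - b.x) * (y - c.y)) / d;
  const double l2 = ((c.y - a.y) * (x - c.x) + (a.x - c.x) * (y - c.y)) / d;
  const double l3 = 1.0 - l1 - l2;
  if (l1 < 0.0 || l2 < 0.0 || l3 < 0.0) return false;
  zhit = l1 * a.z + l2 * b.z + l3 * c.z;
  return true;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                           NumericVector spacing, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nf = F.nrow();
  // Sub-voxel jitter of the ray position avoids exact edge/vertex hits on
  // grid-aligned geometry; it perturbs the inside test only within ~1e-7 voxel.
  const double jx = 1.2345e-7 * spacing[0], jy = 2.3456e-7 * spacing[1],
               jz = 3.4567e-7 * spacing[2];

  std::vector<std::vector<double>> crossings((size_t)nx * ny);
  for (int t = 0; t < nf; ++t) {
    Vec3 a = v3(V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2));
    Vec3 b = v3(V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2));
    Vec3 c = v3(V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2));
    double xmin = std::min({a.x, b.x, c.x}), xmax = std::max({a.x, b.x, c.x});
    double ymin = std::min({a.y, b.y, c.y}), ymax = std::max({a.y, b.y, c.y});
    int i0 = std::max(0, (int)std::ceil((xmin - origin[0] - jx) / spacing[0] - 1e-12));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - origin[0] - jx) / spacing[0] + 1e-12));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1] - jy) / spacing[1] - 1e-12));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - origin[1] - jy) / spacing[1] + 1e-12));
    for (int j = j0; j <= j1; ++j) {
      const double y = origin[1] + j * spacing[1] + jy;
      for (int i = i0; i <= i1; ++i) {
        const double x = origin[0] + i * spacing[0] + jx;
        double zhit;
        if (ray_z_hit(x, y, a, b, c, zhit)) crossings[(size_t)i + (size_t)nx * j].push_back(zhit);
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& zs = crossings[(size_t)i + (size_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // collapse numerically duplicated crossings (ray through a crease)
      std::vector<double> zu;
      for (double z : zs)
        if (zu.empty() || z - zu.back() > 1e-9) zu.push_back(z);
      if (zu.size() % 2 == 1) zu.pop_back();  // unpaired crossing: drop, stay conservative
      for (size_t p = 0; p + 1 < zu.size(); p += 2) {
        int k0 = std::max(0, (int)std::ceil((zu[p] - jz - origin[2]) / spacing[2]));
        int k1 = std::min(nz - 1, (int)std::floor((zu[p + 1] - jz - origin[2]) / spacing[2]));
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_inside_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  LogicalVector out(np);
  const double jx = 1.7321e-7, jy = 2.7183e-7;
  for (int p = 0; p < np; ++p) {
    const double x = P(p, 0) + jx, y = P(p, 1) + jy, z = P(p, 2);
    int cnt = 0;
    for (int t = 0; t < nf; ++t) {
      Vec3 a = v3(V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2));
      Vec3 b = v3(V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2));
      Vec3 c = v3(V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2));
      double zhit;
      if (ray_z_hit(x, y, a, b, c, zhit) && zhit > z) ++cnt;
    }
    out[p] = (cnt % 2 == 1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface extraction.
// Each grid cell is split into 6 tetrahedra sharing the main diagonal; the
// level surface inside each tetrahedron is one or two triangles with vertices
// interpolated on crossing edges. Orientation is fixed at emission time so
// normals point from the "inside" (value > level) outward.
// ---------------------------------------------------------------------------

namespace {

struct MTState {
  std::map<std::pair<long long, long long>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

inline int edge_point(MTState& st, long long ga, long long gb, Vec3 pa, Vec3 pb, double va,
                      double vb, double level) {
  if (ga > gb) {
    std::swap(ga, gb);
    std::swap(pa, pb);
    std::swap(va, vb);
  }
  auto key = std::make_pair(ga, gb);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (level - va) / (vb - va);
  t = std::min(1.0, std::max(0.0, t));
  Vec3 p = add(pa, scale(sub(pb, pa), t));
  int id = (int)st.vx.size();
  st.vx.push_back(p.x);
  st.vy.push_back(p.y);
  st.vz.push_back(p.z);
  st.edge_vertex[key] = id;
  return id;
}

inline void emit_tri(MTState& st, int i, int j, int k, const Vec3& inside_ref) {
  Vec3 a = v3(st.vx[i], st.vy[i], st.vz[i]);
  Vec3 b = v3(st.vx[j], st.vy[j], st.vz[j]);
  Vec3 c = v3(st.vx[k], st.vy[k], st.vz[k]);
  Vec3 n = cross(sub(b, a), sub(c, a));
  if (norm(n) == 0.0) return;  // exactly degenerate
  Vec3 cent = scale(add(add(a, b), c), 1.0 / 3.0);
  if (dot(n, sub(cent, inside_ref)) < 0.0) std::swap(j, k);
  st.f0.push_back(i);
  st.f1.push_back(j);
  st.f2.push_back(k);
}

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double level,
                       NumericVector origin, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // cube corner offsets, bit order (dx, dy, dz)
  const int cdx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // 6-tetrahedron decomposition around the 0-6 diagonal
  const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                          {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  MTState st;

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        double val[8];
        long long gid[8];
        Vec3 pos[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int ci = i + cdx[c], cj = j + cdy[c], ck = k + cdz[c];
          gid[c] = (long long)ci + (long long)nx * (cj + (long long)ny * ck);
          val[c] = field[gid[c]];
          pos[c] = v3(origin[0] + ci * spacing[0], origin[1] + cj * spacing[1],
                      origin[2] + ck * spacing[2]);
          (val[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            idx[c] = tets[t][c];
            in[c] = val[idx[c]] > level;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          Vec3 iref = v3(0, 0, 0);
          int cnt = 0;
          for (int c = 0; c < 4; ++c)
            if (in[c]) {
              iref = add(iref, pos[idx[c]]);
              ++cnt;
            }
          iref = scale(iref, 1.0 / cnt);
          auto ep = [&](int a, int b) {
            return edge_point(st, gid[idx[a]], gid[idx[b]], pos[idx[a]], pos[idx[b]], val[idx[a]],
                              val[idx[b]], level);
          };
          if (nin == 1 || nin == 3) {
            int solo = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (nin == 1)) solo = c;
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != solo) o[m++] = c;
            emit_tri(st, ep(solo, o[0]), ep(solo, o[1]), ep(solo, o[2]), iref);
          } else {  // nin == 2: quad
            int a = -1, b = -1, c1 = -1, c2 = -1;
            for (int c = 0; c < 4; ++c)
              (in[c] ? (a < 0 ? a : b) : (c1 < 0 ? c1 : c2)) = c;
            const int pac = ep(a, c1), pad = ep(a, c2), pbc = ep(b, c1), pbd = ep(b, c2);
            emit_tri(st, pac, pad, pbd, iref);
            emit_tri(st, pac, pbd, pbc, iref);
          }
        }
      }
    }
  }

  const int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vm(i, 0) = st.vx[i];
    Vm(i, 1) = st.vy[i];
    Vm(i, 2) = st.vz[i];
  }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = st.f0[i];
    Fm(i, 1) = st.f1[i];
    Fm(i, 2) = st.f2[i];
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dims, NumericVector origin,
                            NumericVector spacing, NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double fx = (pts(p, 0) - origin[0]) / spacing[0];
    const double fy = (pts(p, 1) - origin[1]) / spacing[1];
    const double fz = (pts(p, 2) - origin[2]) / spacing[2];
    const int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < -1 || i > nx - 1 || j < -1 || j > ny - 1 || k < -1 || k > nz - 1) {
      out[p] = 0.0;
      continue;
    }
    const double tx = fx - i, ty = fy - j, tz = fz - k;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const int ii = i + dx, jj = j + dy, kk = k + dz;
          double v = 0.0;  // outside the grid counts as empty
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            v = field[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          const double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) * (dz ? tz : 1 - tz);
          acc += w * v;
        }
    out[p] = acc;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) x = parent[x] = parent[parent[x]];
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  IntegerMatrix lab(nr, nc);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j)) continue;
      int best = 0;
      // 8-neighbors already visited in column-major scan order
      const int di[4] = {-1, -1, 0, 1}, dj[4] = {0, -1, -1, -1};
      for (int q = 0; q < 4; ++q) {
        const int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0)
            best = l;
          else
            unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  // second pass: flatten and renumber densely
  std::map<int, int> dense;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        const int r = find(lab(i, j));
        auto it = dense.find(r);
        int id;
        if (it == dense.end()) {
          id = (int)dense.size() + 1;
          dense[r] = id;
        } else
          id = it->second;
        lab(i, j) = id;
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Implicit tube network: distance to a polyline "capsule chain" with linearly
// interpolated radius, chains combined by polynomial smooth-minimum.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_tube_union_sdf(NumericMatrix pts, List chains, double blend) {
  const int np = pts.nrow();
  const int nch = chains.size();
  std::vector<NumericMatrix> C(nch);
  std::vector<NumericVector> R(nch);
  std::vector<double> bx0(nch), bx1(nch), by0(nch), by1(nch), bz0(nch), bz1(nch);
  for (int c = 0; c < nch; ++c) {
    List ch = chains[c];
    C[c] = as<NumericMatrix>(ch["centers"]);
    R[c] = as<NumericVector>(ch["radii"]);
    double maxr = 0.0;
    for (int q = 0; q < R[c].size(); ++q) maxr = std::max(maxr, R[c][q]);
    const double margin = maxr + blend + 1.0;
    bx0[c] = R_PosInf; bx1[c] = R_NegInf; by0[c] = R_PosInf;
    by1[c] = R_NegInf; bz0[c] = R_PosInf; bz1[c] = R_NegInf;
    for (int q = 0; q < C[c].nrow(); ++q) {
      bx0[c] = std::min(bx0[c], C[c](q, 0)); bx1[c] = std::max(bx1[c], C[c](q, 0));
      by0[c] = std::min(by0[c], C[c](q, 1)); by1[c] = std::max(by1[c], C[c](q, 1));
      bz0[c] = std::min(bz0[c], C[c](q, 2)); bz1[c] = std::max(bz1[c], C[c](q, 2));
    }
    bx0[c] -= margin; bx1[c] += margin; by0[c] -= margin;
    by1[c] += margin; bz0[c] -= margin; bz1[c] += margin;
  }

  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double acc = R_PosInf;
    for (int c = 0; c < nch; ++c) {
      double d;
      if (x < bx0[c] || x > bx1[c] || y < by0[c] || y > by1[c] || z < bz0[c] || z > bz1[c]) {
        d = blend + 1.0;  // provably far: participates as plain min only
      } else {
        d = R_PosInf;
        const NumericMatrix& cc = C[c];
        const NumericVector& rr = R[c];
        for (int s = 0; s + 1 < cc.nrow(); ++s) {
          const double ax = cc(s, 0), ay = cc(s, 1), az = cc(s, 2);
          const double bx = cc(s + 1, 0), by = cc(s + 1, 1), bz = cc(s + 1, 2);
          const double ex = bx - ax, ey = by - ay, ez = bz - az;
          const double len2 = ex * ex + ey * ey + ez * ez;
          double t = 0.0;
          if (len2 > 0)
            t = std::min(1.0, std::max(0.0, ((x - ax) * ex + (y - ay) * ey + (z - az) * ez) / len2));
          const double px = ax + t * ex - x, py = ay + t * ey - y, pz = az + t * ez - z;
          const double dist = std::sqrt(px * px + py * py + pz * pz) - (rr[s] + t * (rr[s + 1] - rr[s]));
          d = std::min(d, dist);
        }
      }
      if (blend > 0 && std::isfinite(acc)) {
        const double h = std::max(blend - std::fabs(acc - d), 0.0) / blend;
        acc = std::min(acc, d) - h * h * blend * 0.25;
      } else {
        acc = std::min(acc, d);
      }
    }
    out[p] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Closest point-to-triangle distance with a median-split AABB tree.
// ---------------------------------------------------------------------------

namespace {

// Ericson, Real-Time Collision Detection: closest point on triangle to p.
inline double tri_dist2(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  const Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) {
    const Vec3 d = ap;
    return dot(d, d);
  }
  const Vec3 bp = sub(p, b);
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) {
    const Vec3 d = bp;
    return dot(d, d);
  }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    const double v = d1 / (d1 - d3);
    const Vec3 d = sub(p, add(a, scale(ab, v)));
    return dot(d, d);
  }
  const Vec3 cp = sub(p, c);
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) {
    const Vec3 d = cp;
    return dot(d, d);
  }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    const double w = d2 / (d2 - d6);
    const Vec3 d = sub(p, add(a, scale(ac, w)));
    return dot(d, d);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    const Vec3 d = sub(p, add(b, scale(sub(c, b), w)));
    return dot(d, d);
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  const Vec3 d = sub(p, add(a, add(scale(ab, v), scale(ac, w))));
  return dot(d, d);
}

struct BVHNode {
  double lo[3], hi[3];
  int left = -1, right = -1;  // children, or
  int begin = 0, end = 0;     // triangle index range when leaf
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
  const NumericMatrix* V;
  const IntegerMatrix* F;
  std::vector<double> cx, cy, cz;

  int build(int begin, int end) {
    BVHNode nd;
    nd.lo[0] = nd.lo[1] = nd.lo[2] = R_PosInf;
    nd.hi[0] = nd.hi[1] = nd.hi[2] = R_NegInf;
    for (int q = begin; q < end; ++q) {
      const int t = order[q];
      for (int c = 0; c < 3; ++c) {
        const int vi = (*F)(t, c);
        const double co[3] = {(*V)(vi, 0), (*V)(vi, 1), (*V)(vi, 2)};
        for (int ax = 0; ax < 3; ++ax) {
          nd.lo[ax] = std::min(nd.lo[ax], co[ax]);
          nd.hi[ax] = std::max(nd.hi[ax], co[ax]);
        }
      }
    }
    const int id = (int)nodes.size();
    nodes.push_back(nd);
    if (end - begin <= 8) {
      nodes[id].begin = begin;
      nodes[id].end = end;
      return id;
    }
    int ax = 0;
    double ext = nd.hi[0] - nd.lo[0];
    for (int a = 1; a < 3; ++a)
      if (nd.hi[a] - nd.lo[a] > ext) {
        ext = nd.hi[a] - nd.lo[a];
        ax = a;
      }
    const int mid = (begin + end) / 2;
    const std::vector<double>& cen = (ax == 0 ? cx : (ax == 1 ? cy : cz));
    std::nth_element(order.begin() + begin, order.begin() + mid, order.begin() + end,
                     [&](int a, int b) { return cen[a] < cen[b]; });
    const int l = build(begin, mid);
    const int r = build(mid, end);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  double box_dist2(const BVHNode& nd, const Vec3& p) const {
    double d2 = 0.0;
    const double co[3] = {p.x, p.y, p.z};
    for (int a = 0; a < 3; ++a) {
      double d = 0.0;
      if (co[a] < nd.lo[a]) d = nd.lo[a] - co[a];
      else if (co[a] > nd.hi[a]) d = co[a] - nd.hi[a];
      d2 += d * d;
    }
    return d2;
  }

  void query(int id, const Vec3& p, double& best) const {
    const BVHNode& nd = nodes[id];
    if (box_dist2(nd, p) >= best) return;
    if (nd.left < 0) {
      for (int q = nd.begin; q < nd.end; ++q) {
        const int t = order[q];
        const Vec3 a = v3((*V)((*F)(t, 0), 0), (*V)((*F)(t, 0), 1), (*V)((*F)(t, 0), 2));
        const Vec3 b = v3((*V)((*F)(t, 1), 0), (*V)((*F)(t, 1), 1), (*V)((*F)(t, 1), 2));
        const Vec3 c = v3((*V)((*F)(t, 2), 0), (*V)((*F)(t, 2), 1), (*V)((*F)(t, 2), 2));
        best = std::min(best, tri_dist2(p, a, b, c));
      }
      return;
    }
    const double dl = box_dist2(nodes[nd.left], p), dr = box_dist2(nodes[nd.right], p);
    if (dl < dr) {
      query(nd.left, p, best);
      query(nd.right, p, best);
    } else {
      query(nd.right, p, best);
      query(nd.left, p, best);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  BVH bvh;
  bvh.V = &V;
  bvh.F = &F;
  const int nf = F.nrow();
  bvh.order.resize(nf);
  bvh.cx.resize(nf);
  bvh.cy.resize(nf);
  bvh.cz.resize(nf);
  for (int t = 0; t < nf; ++t) {
    bvh.order[t] = t;
    bvh.cx[t] = (V(F(t, 0), 0) + V(F(t, 1), 0) + V(F(t, 2), 0)) / 3.0;
    bvh.cy[t] = (V(F(t, 0), 1) + V(F(t, 1), 1) + V(F(t, 2), 1)) / 3.0;
    bvh.cz[t] = (V(F(t, 0), 2) + V(F(t, 1), 2) + V(F(t, 2), 2)) / 3.0;
  }
  bvh.build(0, nf);
  const int np = P.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    bvh.query(0, v3(P(p, 0), P(p, 1), P(p, 2)), best);
    out[p] = std::sqrt(best);
  }
  return out;
}
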