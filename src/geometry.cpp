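// Compiled mesh kernels: ray-parity voxelization, lattice surface extraction,
// closest point on a triangulated surface, face connectivity and orientation.
// Coordinates are millimetres throughout.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Voxelization by vertical ray parity.
//
// Column centers are (origin + (i+1/2)h, origin + (j+1/2)h); for every column
// the z-crossings with the surface are collected and voxel centers falling in
// odd-parity intervals are marked inside.  Points exactly on a shared
// projected edge are assigned to exactly one incident triangle by a top-left
// style fill rule, so parity stays exact on axis-aligned fixtures.
// ---------------------------------------------------------------------------

static inline bool edge_counts(double ax, double ay, double bx, double by) {
  // fill rule: a boundary point on directed edge (a->b) is owned by the
  // triangle where the edge goes "down" (or leftward when horizontal)
  if (ay != by) return ay > by;
  return ax < bx;
}

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, double h,
                           int nx, int ny, int nz) {
  const R_xlen_t nf = F.nrow();
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // scale-aware tolerance: edge functions within eps of zero are treated as
  // boundary hits and resolved by the ownership rule, so the two triangles
  // sharing an edge agree on who owns a ray through it despite round-off
  double scale = 1.0;
  for (int v = 0; v < V.nrow(); ++v)
    for (int d = 0; d < 2; ++d)
      scale = std::max(scale, std::fabs(V(v, d)));
  const double eps = 1e-12 * scale * scale;

  // crossings as (column index, z) pairs
  std::vector<std::pair<int64_t, double> > cross;
  cross.reserve((size_t)nf);

  for (R_xlen_t f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    double bx = V(ib, 0), by = V(ib, 1), bz = V(ib, 2);
    double cx = V(ic, 0), cy = V(ic, 1), cz = V(ic, 2);

    double w = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(w) <= eps) continue;    // vertical triangle: tangent to ray
    if (w < 0) {                          // normalize to CCW in the xy plane
      std::swap(bx, cx); std::swap(by, cy); std::swap(bz, cz);
      w = -w;
    }

    double minx = std::min(ax, std::min(bx, cx));
    double maxx = std::max(ax, std::max(bx, cx));
    double miny = std::min(ay, std::min(by, cy));
    double maxy = std::max(ay, std::max(by, cy));

    int i0 = (int)std::ceil((minx - ox) / h - 0.5);
    int i1 = (int)std::floor((maxx - ox) / h - 0.5);
    int j0 = (int)std::ceil((miny - oy) / h - 0.5);
    int j1 = (int)std::floor((maxy - oy) / h - 0.5);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 >= nx) i1 = nx - 1;
    if (j1 >= ny) j1 = ny - 1;

    for (int j = j0; j <= j1; ++j) {
      double py = oy + (j + 0.5) * h;
      for (int i = i0; i <= i1; ++i) {
        double px = ox + (i + 0.5) * h;
        double e0 = (cx - bx) * (py - by) - (cy - by) * (px - bx); // vs a
        double e1 = (ax - cx) * (py - cy) - (ay - cy) * (px - cx); // vs b
        double e2 = (bx - ax) * (py - ay) - (by - ay) * (px - ax); // vs c
        bool z0 = std::fabs(e0) <= eps, z1 = std::fabs(e1) <= eps,
             z2 = std::fabs(e2) <= eps;
        bool in = ((e0 > 0 && !z0) || (z0 && edge_counts(bx, by, cx, cy))) &&
                  ((e1 > 0 && !z1) || (z1 && edge_counts(cx, cy, ax, ay))) &&
                  ((e2 > 0 && !z2) || (z2 && edge_counts(ax, ay, bx, by)));
        if (!in) continue;
        double la = e0 / w, lb = e1 / w, lc = e2 / w;
        double z = la * az + lb * bz + lc * cz;
        cross.push_back(std::make_pair((int64_t)j * nx + i, z));
      }
    }
  }

  std::sort(cross.begin(), cross.end());

  LogicalVector inside((R_xlen_t)nx * ny * nz);
  std::fill(inside.begin(), inside.end(), FALSE);

  size_t s = 0;
  while (s < cross.size()) {
    size_t e = s;
    while (e < cross.size() && cross[e].first == cross[s].first) ++e;
    int64_t col = cross[s].first;
    int i = (int)(col % nx), j = (int)(col / nx);
    // pair up crossings; an unpaired trailing crossing (degenerate tangency)
    // is ignored
    for (size_t p = s; p + 1 < e; p += 2) {
      double z0 = cross[p].second, z1 = cross[p + 1].second;
      int k0 = (int)std::ceil((z0 - oz) / h - 0.5);
      int k1 = (int)std::floor((z1 - oz) / h - 0.5);
      if (k0 < 0) k0 = 0;
      if (k1 >= nz) k1 = nz - 1;
      for (int k = k0; k <= k1; ++k)
        inside[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = TRUE;
    }
    s = e;
  }
  return inside;
}

// ---------------------------------------------------------------------------
// Surface extraction: boundary quads between inside and outside voxels,
// triangulated, outward-oriented, vertices merged on the corner lattice.
// ---------------------------------------------------------------------------

struct SurfBuilder {
  std::unordered_map<int64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  double ox, oy, oz, h;
  int64_t sx, sy; // lattice strides

  int corner(int i, int j, int k) {
    int64_t key = (int64_t)i + sx * ((int64_t)j + sy * (int64_t)k);
    std::unordered_map<int64_t, int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap[key] = id;
    vx.push_back(ox + i * h);
    vy.push_back(oy + j * h);
    vz.push_back(oz + k * h);
    return id;
  }
  void quad(int a, int b, int c, int d) { // CCW seen from outside
    fa.push_back(a); fb.push_back(b); fc.push_back(c);
    fa.push_back(a); fb.push_back(c); fc.push_back(d);
  }
};

// [[Rcpp::export]]
List cpp_extract_surface(LogicalVector inside, int nx, int ny, int nz,
                         NumericVector origin, double h) {
  SurfBuilder B;
  B.ox = origin[0]; B.oy = origin[1]; B.oz = origin[2]; B.h = h;
  B.sx = (int64_t)nx + 1; B.sy = (int64_t)ny + 1;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = (R_xlen_t)k * sxy + (R_xlen_t)j * nx + i;
        if (!inside[id]) continue;
        bool xm = (i == 0)      || !inside[id - 1];
        bool xp = (i == nx - 1) || !inside[id + 1];
        bool ym = (j == 0)      || !inside[id - nx];
        bool yp = (j == ny - 1) || !inside[id + nx];
        bool zm = (k == 0)      || !inside[id - sxy];
        bool zp = (k == nz - 1) || !inside[id + sxy];
        if (xp) B.quad(B.corner(i+1,j,k),   B.corner(i+1,j+1,k),
                       B.corner(i+1,j+1,k+1), B.corner(i+1,j,k+1));
        if (xm) B.quad(B.corner(i,j,k),     B.corner(i,j,k+1),
                       B.corner(i,j+1,k+1), B.corner(i,j+1,k));
        if (yp) B.quad(B.corner(i,j+1,k),   B.corner(i,j+1,k+1),
                       B.corner(i+1,j+1,k+1), B.corner(i+1,j+1,k));
        if (ym) B.quad(B.corner(i,j,k),     B.corner(i+1,j,k),
                       B.corner(i+1,j,k+1), B.corner(i,j,k+1));
        if (zp) B.quad(B.corner(i,j,k+1),   B.corner(i+1,j,k+1),
                       B.corner(i+1,j+1,k+1), B.corner(i,j+1,k+1));
        if (zm) B.quad(B.corner(i,j,k),     B.corner(i,j+1,k),
                       B.corner(i+1,j+1,k), B.corner(i+1,j,k));
      }

  int nvert = (int)B.vx.size(), nface = (int)B.fa.size();
  NumericMatrix V(nvert, 3);
  for (int v = 0; v < nvert; ++v) {
    V(v, 0) = B.vx[v]; V(v, 1) = B.vy[v]; V(v, 2) = B.vz[v];
  }
  IntegerMatrix F(nface, 3);
  for (int f = 0; f < nface; ++f) {
    F(f, 0) = B.fa[f] + 1; F(f, 1) = B.fb[f] + 1; F(f, 2) = B.fc[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export]]
IntegerVector cpp_voxel_components(LogicalVector inside, int nx, int ny, int nz) {
  // 6-connectivity labels, 0 = outside, components numbered from 1
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, sxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s0 = 0; s0 < n; ++s0) {
    if (!inside[s0] || lab[s0]) continue;
    ++next;
    stack.push_back(s0);
    lab[s0] = next;
    while (!stack.empty()) {
      R_xlen_t id = stack.back(); stack.pop_back();
      int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / sxy);
      const R_xlen_t nb[6] = { id - 1, id + 1, id - nx, id + nx, id - sxy, id + sxy };
      const bool ok[6] = { i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0, k < nz - 1 };
      for (int d = 0; d < 6; ++d)
        if (ok[d] && inside[nb[d]] && !lab[nb[d]]) {
          lab[nb[d]] = next;
          stack.push_back(nb[d]);
        }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Face connectivity (shared undirected edge), union-find.
// ---------------------------------------------------------------------------

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

static inline int64_t ekey(int a, int b, int64_t nv) {
  return a < b ? (int64_t)a * nv + b : (int64_t)b * nv + a;
}

// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nv) {
  int nf = F.nrow();
  UF uf(nf);
  std::unordered_map<int64_t, int> first;
  first.reserve((size_t)nf * 3);
  for (int f = 0; f < nf; ++f) {
    int v[3] = { F(f, 0), F(f, 1), F(f, 2) };
    for (int e = 0; e < 3; ++e) {
      int64_t k = ekey(v[e], v[(e + 1) % 3], nv + 1);
      std::unordered_map<int64_t, int>::iterator it = first.find(k);
      if (it == first.end()) first[k] = f; else uf.unite(f, it->second);
    }
  }
  // compact labels
  IntegerVector lab(nf);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int f = 0; f < nf; ++f) {
    int r = uf.find(f);
    std::unordered_map<int, int>::iterator it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[f] = next; }
    else lab[f] = it->second;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Edge statistics + consistent orientation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_edge_stats(IntegerMatrix F, int nv) {
  int nf = F.nrow();
  std::unordered_map<int64_t, int> undirected;   // incidence counts
  std::unordered_map<int64_t, int> directed;     // signed balance
  undirected.reserve((size_t)nf * 3);
  directed.reserve((size_t)nf * 3);
  const int64_t NV = nv + 1;
  for (int f = 0; f < nf; ++f) {
    int v[3] = { F(f, 0), F(f, 1), F(f, 2) };
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      undirected[ekey(a, b, NV)] += 1;
      directed[(int64_t)std::min(a, b) * NV + std::max(a, b)] += (a < b) ? 1 : -1;
    }
  }
  int n_boundary = 0, n_nonmanifold = 0, n_edges = (int)undirected.size();
  for (std::unordered_map<int64_t, int>::iterator it = undirected.begin();
       it != undirected.end(); ++it) {
    if (it->second == 1) ++n_boundary;
    else if (it->second > 2) ++n_nonmanifold;
  }
  bool balanced = true;
  for (std::unordered_map<int64_t, int>::iterator it = directed.begin();
       it != directed.end(); ++it)
    if (it->second != 0) { balanced = false; break; }
  return List::create(_["n_edges"] = n_edges,
                      _["n_boundary_edges"] = n_boundary,
                      _["n_nonmanifold_edges"] = n_nonmanifold,
                      _["directed_balanced"] = balanced);
}

// [[Rcpp::export]]
List cpp_orient_faces(IntegerMatrix F, int nv) {
  // Flip faces so that every manifold shared edge is traversed in opposite
  // directions by its two faces.  Traversal does not cross edges with more
  // than two incident faces.  Returns possibly-flipped faces and a flag for
  // orientation conflicts (non-orientable surface).
  int nf = F.nrow();
  const int64_t NV = nv + 1;
  std::unordered_map<int64_t, std::vector<int> > e2f;
  e2f.reserve((size_t)nf * 3);
  for (int f = 0; f < nf; ++f) {
    int v[3] = { F(f, 0), F(f, 1), F(f, 2) };
    for (int e = 0; e < 3; ++e)
      e2f[ekey(v[e], v[(e + 1) % 3], NV)].push_back(f);
  }
  IntegerMatrix G(clone(F));
  std::vector<char> seen(nf, 0), flipped(nf, 0);
  bool conflict = false;
  std::queue<int> q;
  for (int s = 0; s < nf; ++s) {
    if (seen[s]) continue;
    seen[s] = 1;
    q.push(s);
    while (!q.empty()) {
      int f = q.front(); q.pop();
      int v[3] = { G(f, 0), G(f, 1), G(f, 2) };
      for (int e = 0; e < 3; ++e) {
        int a = v[e], b = v[(e + 1) % 3];
        std::vector<int>& nbrs = e2f[ekey(a, b, NV)];
        if (nbrs.size() != 2) continue;
        for (size_t t = 0; t < nbrs.size(); ++t) {
          int g = nbrs[t];
          if (g == f) continue;
          // does g (current winding) traverse a->b or b->a?
          int w[3] = { G(g, 0), G(g, 1), G(g, 2) };
          bool same = false;
          for (int e2 = 0; e2 < 3; ++e2)
            if (w[e2] == a && w[(e2 + 1) % 3] == b) { same = true; break; }
          if (!seen[g]) {
            if (same) { // same direction => inconsistent, flip g
              std::swap(G(g, 1), G(g, 2));
              flipped[g] = 1;
            }
            seen[g] = 1;
            q.push(g);
          } else if (same) {
            conflict = true;
          }
        }
      }
    }
  }
  int nflip = 0;
  for (int f = 0; f < nf; ++f) nflip += flipped[f];
  return List::create(_["faces"] = G, _["n_flipped"] = nflip,
                      _["conflict"] = conflict);
}

// ---------------------------------------------------------------------------
// Closest point on a triangulated surface, uniform-grid accelerated.
// ---------------------------------------------------------------------------

static inline void closest_on_tri(const double* p, const double* a,
                                  const double* b, const double* c,
                                  double* out) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i] = a[i] + v*ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i] = a[i] + w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i] = b[i] + w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Vm, IntegerMatrix Fm, NumericMatrix Qm) {
  const int nf = Fm.nrow(), nq = Qm.nrow(), nv = Vm.nrow();
  // copy into flat arrays: avoids SEXP accessor overhead in the hot loops
  std::vector<double> V((size_t)nv * 3), Q((size_t)nq * 3);
  std::vector<int> F((size_t)nf * 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) V[(size_t)v * 3 + d] = Vm(v, d);
  for (int q = 0; q < nq; ++q)
    for (int d = 0; d < 3; ++d) Q[(size_t)q * 3 + d] = Qm(q, d);
  for (int f = 0; f < nf; ++f)
    for (int d = 0; d < 3; ++d) F[(size_t)f * 3 + d] = Fm(f, d) - 1;

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) {
      double x = V[(size_t)v * 3 + d];
      if (x < lo[d]) lo[d] = x;
      if (x > hi[d]) hi[d] = x;
    }
  double ext = std::max(hi[0]-lo[0], std::max(hi[1]-lo[1], hi[2]-lo[2]));
  if (ext <= 0) ext = 1.0;
  // target a few triangles per occupied cell
  double cell = ext / std::max(4.0, std::cbrt((double)nf) * 1.5);
  int gx = (int)std::floor((hi[0]-lo[0]) / cell) + 1;
  int gy = (int)std::floor((hi[1]-lo[1]) / cell) + 1;
  int gz = (int)std::floor((hi[2]-lo[2]) / cell) + 1;

  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve((size_t)nf);
  const int64_t GX = gx, GXY = (int64_t)gx * gy;
  for (int f = 0; f < nf; ++f) {
    const int* vi = &F[(size_t)f * 3];
    double tl[3], th[3];
    for (int d = 0; d < 3; ++d) {
      double x0 = V[(size_t)vi[0]*3+d], x1 = V[(size_t)vi[1]*3+d],
             x2 = V[(size_t)vi[2]*3+d];
      tl[d] = std::min(x0, std::min(x1, x2));
      th[d] = std::max(x0, std::max(x1, x2));
    }
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = (int)std::floor((tl[d]-lo[d]) / cell);
      c1[d] = (int)std::floor((th[d]-lo[d]) / cell);
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          grid[(int64_t)i + GX*j + GXY*k].push_back(f);
  }

  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);
  int maxshell = std::max(gx, std::max(gy, gz)) + 1;

  for (int q = 0; q < nq; ++q) {
    double p[3] = { Q[(size_t)q*3], Q[(size_t)q*3+1], Q[(size_t)q*3+2] };
    int qc[3];
    for (int d = 0; d < 3; ++d) {
      int c = (int)std::floor((p[d]-lo[d]) / cell);
      qc[d] = c;
    }
    double best = R_PosInf, bp[3] = {0,0,0};
    int bf = -1;
    for (int r = 0; r <= maxshell; ++r) {
      bool any = false;
      for (int k = qc[2]-r; k <= qc[2]+r; ++k) {
        if (k < 0 || k >= gz) continue;
        for (int j = qc[1]-r; j <= qc[1]+r; ++j) {
          if (j < 0 || j >= gy) continue;
          for (int i = qc[0]-r; i <= qc[0]+r; ++i) {
            if (i < 0 || i >= gx) continue;
            int cheb = std::max(std::abs(i-qc[0]),
                       std::max(std::abs(j-qc[1]), std::abs(k-qc[2])));
            if (cheb != r) continue;
            std::unordered_map<int64_t, std::vector<int> >::iterator it =
              grid.find((int64_t)i + GX*j + GXY*k);
            if (it == grid.end()) continue;
            any = true;
            std::vector<int>& tris = it->second;
            for (size_t t = 0; t < tris.size(); ++t) {
              int f = tris[t];
              const int* vi = &F[(size_t)f * 3];
              const double* a = &V[(size_t)vi[0] * 3];
              const double* b = &V[(size_t)vi[1] * 3];
              const double* c = &V[(size_t)vi[2] * 3];
              double cp[3];
              closest_on_tri(p, a, b, c, cp);
              double d2 = 0;
              for (int d = 0; d < 3; ++d) d2 += (cp[d]-p[d])*(cp[d]-p[d]);
              if (d2 < best) {
                best = d2; bf = f;
                for (int d = 0; d < 3; ++d) bp[d] = cp[d];
              }
            }
          }
        }
      }
      // cells beyond shell r are at least r*cell away from p's cell
      if (bf >= 0 && best <= (double)r * cell * (double)r * cell) break;
      (void)any;
    }
    P(q,0)=bp[0]; P(q,1)=bp[1]; P(q,2)=bp[2];
    D[q] = std::sqrt(best);
    FI[q] = bf + 1;
  }
  return List::create(_["points"] = P, _["dist"] = D, _["face"] = FI);
}
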