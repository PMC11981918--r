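// Triangle-mesh geometry kernels: point-to-surface distance, grid-accelerated
// ray casting, shape-diameter thickness, face connectivity.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
#include <functional>
#include <unordered_map>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 vscale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// squared distance from point p to triangle (a, b, c); Ericson's method
static double point_tri_dist2(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { Vec3 d = vsub(p, a); return vdot(d, d); }
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { Vec3 d = vsub(p, b); return vdot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    Vec3 q = vadd(a, vscale(ab, v)); Vec3 d = vsub(p, q); return vdot(d, d);
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { Vec3 d = vsub(p, c); return vdot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    Vec3 q = vadd(a, vscale(ac, w)); Vec3 d = vsub(p, q); return vdot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 q = vadd(b, vscale(vsub(c, b), w)); Vec3 d = vsub(p, q); return vdot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  Vec3 q = vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
  Vec3 d = vsub(p, q);
  return vdot(d, d);
}

// Unsigned distance from each point to the nearest point on the mesh surface.
// Quick rejection against face bounding spheres keeps this near-linear for
// meshes where points lie close to the surface.
// [[Rcpp::export(name = ".cpp_point_mesh_distance")]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  std::vector<Vec3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = {V(i, 0), V(i, 1), V(i, 2)};
  std::vector<Vec3> cen(nf);
  std::vector<double> rad(nf);
  for (int f = 0; f < nf; ++f) {
    const Vec3 &a = verts[F(f, 0) - 1], &b = verts[F(f, 1) - 1], &c = verts[F(f, 2) - 1];
    Vec3 g = vscale(vadd(a, vadd(b, c)), 1.0 / 3.0);
    cen[f] = g;
    rad[f] = std::sqrt(std::max({vdot(vsub(a, g), vsub(a, g)),
                                 vdot(vsub(b, g), vsub(b, g)),
                                 vdot(vsub(c, g), vsub(c, g))}));
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    Vec3 q = {P(p, 0), P(p, 1), P(p, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      Vec3 d = vsub(q, cen[f]);
      double lo = std::sqrt(vdot(d, d)) - rad[f];
      if (lo * lo >= best && lo > 0) continue;
      double d2 = point_tri_dist2(q, verts[F(f, 0) - 1], verts[F(f, 1) - 1], verts[F(f, 2) - 1]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ---- grid-accelerated ray casting -----------------------------------------

struct FaceGrid {
  Vec3 lo, hi;
  double cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;
  int bin_of(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

static FaceGrid build_grid(const std::vector<Vec3> &verts, const IntegerMatrix &F) {
  FaceGrid g;
  g.lo = {R_PosInf, R_PosInf, R_PosInf};
  g.hi = {R_NegInf, R_NegInf, R_NegInf};
  for (const auto &v : verts) {
    g.lo.x = std::min(g.lo.x, v.x); g.lo.y = std::min(g.lo.y, v.y); g.lo.z = std::min(g.lo.z, v.z);
    g.hi.x = std::max(g.hi.x, v.x); g.hi.y = std::max(g.hi.y, v.y); g.hi.z = std::max(g.hi.z, v.z);
  }
  double ext = std::max({g.hi.x - g.lo.x, g.hi.y - g.lo.y, g.hi.z - g.lo.z, 1e-9});
  int nf = F.nrow();
  // aim for a handful of faces per occupied cell
  double target = std::cbrt((double)std::max(nf, 1)) * 0.75;
  g.cell = std::max(ext / std::max(8.0, std::min(target, 96.0)), 1e-9);
  // small epsilon pad so border faces fall inside
  g.lo.x -= 1e-6 * ext; g.lo.y -= 1e-6 * ext; g.lo.z -= 1e-6 * ext;
  g.nx = (int)std::floor((g.hi.x - g.lo.x) / g.cell) + 2;
  g.ny = (int)std::floor((g.hi.y - g.lo.y) / g.cell) + 2;
  g.nz = (int)std::floor((g.hi.z - g.lo.z) / g.cell) + 2;
  g.bins.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int f = 0; f < nf; ++f) {
    const Vec3 &a = verts[F(f, 0) - 1], &b = verts[F(f, 1) - 1], &c = verts[F(f, 2) - 1];
    double fx0 = std::min({a.x, b.x, c.x}), fx1 = std::max({a.x, b.x, c.x});
    double fy0 = std::min({a.y, b.y, c.y}), fy1 = std::max({a.y, b.y, c.y});
    double fz0 = std::min({a.z, b.z, c.z}), fz1 = std::max({a.z, b.z, c.z});
    int i0 = (int)((fx0 - g.lo.x) / g.cell), i1 = (int)((fx1 - g.lo.x) / g.cell);
    int j0 = (int)((fy0 - g.lo.y) / g.cell), j1 = (int)((fy1 - g.lo.y) / g.cell);
    int k0 = (int)((fz0 - g.lo.z) / g.cell), k1 = (int)((fz1 - g.lo.z) / g.cell);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.bins[g.bin_of(i, j, k)].push_back(f);
  }
  return g;
}

// Moeller-Trumbore; returns t >= 0 or -1
static double ray_tri(const Vec3 &o, const Vec3 &d,
                      const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  const double eps = 1e-12;
  Vec3 e1 = vsub(b, a), e2 = vsub(c, a);
  Vec3 pv = vcross(d, e2);
  double det = vdot(e1, pv);
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  Vec3 tv = vsub(o, a);
  double u = vdot(tv, pv) * inv;
  if (u < -1e-9 || u > 1 + 1e-9) return -1.0;
  Vec3 qv = vcross(tv, e1);
  double v = vdot(d, qv) * inv;
  if (v < -1e-9 || u + v > 1 + 1e-9) return -1.0;
  double t = vdot(e2, qv) * inv;
  return t >= 0 ? t : -1.0;
}

// first hit along the ray via 3-D DDA over the face grid; returns t and face
static bool grid_ray_first_hit(const FaceGrid &g, const std::vector<Vec3> &verts,
                               const IntegerMatrix &F, const Vec3 &o, const Vec3 &d,
                               int skip_face, double t_min, double &t_hit, int &f_hit) {
  // clip ray to grid box
  double t0 = 0, t1 = R_PosInf;
  const double glox[3] = {g.lo.x, g.lo.y, g.lo.z};
  const double ghix[3] = {g.lo.x + g.nx * g.cell, g.lo.y + g.ny * g.cell, g.lo.z + g.nz * g.cell};
  const double oa[3] = {o.x, o.y, o.z}, da[3] = {d.x, d.y, d.z};
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(da[ax]) < 1e-15) {
      if (oa[ax] < glox[ax] || oa[ax] > ghix[ax]) return false;
    } else {
      double ta = (glox[ax] - oa[ax]) / da[ax], tb = (ghix[ax] - oa[ax]) / da[ax];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t0 > t1) return false;
  Vec3 p = vadd(o, vscale(d, t0 + 1e-12));
  int i = (int)((p.x - g.lo.x) / g.cell), j = (int)((p.y - g.lo.y) / g.cell),
      k = (int)((p.z - g.lo.z) / g.cell);
  i = std::min(std::max(i, 0), g.nx - 1);
  j = std::min(std::max(j, 0), g.ny - 1);
  k = std::min(std::max(k, 0), g.nz - 1);
  int si = d.x > 0 ? 1 : -1, sj = d.y > 0 ? 1 : -1, sk = d.z > 0 ? 1 : -1;
  auto next_t = [&](double lo_crd, double ocrd, double dcrd, int idx, int step) {
    if (std::fabs(dcrd) < 1e-15) return R_PosInf;
    double edge = lo_crd + (idx + (step > 0 ? 1 : 0)) * g.cell;
    return (edge - ocrd) / dcrd;
  };
  double tx = next_t(g.lo.x, o.x, d.x, i, si);
  double ty = next_t(g.lo.y, o.y, d.y, j, sj);
  double tz = next_t(g.lo.z, o.z, d.z, k, sk);
  double dtx = std::fabs(d.x) < 1e-15 ? R_PosInf : g.cell / std::fabs(d.x);
  double dty = std::fabs(d.y) < 1e-15 ? R_PosInf : g.cell / std::fabs(d.y);
  double dtz = std::fabs(d.z) < 1e-15 ? R_PosInf : g.cell / std::fabs(d.z);

  double best = R_PosInf;
  int best_f = -1;
  double cell_exit;
  while (true) {
    const auto &bin = g.bins[g.bin_of(i, j, k)];
    for (int f : bin) {
      if (f == skip_face) continue;
      double t = ray_tri(o, d, verts[F(f, 0) - 1], verts[F(f, 1) - 1], verts[F(f, 2) - 1]);
      if (t > t_min && t < best) { best = t; best_f = f; }
    }
    cell_exit = std::min({tx, ty, tz});
    if (best <= cell_exit) break;  // nearest hit cannot be in a later cell
    if (tx <= ty && tx <= tz) { i += si; tx += dtx; if (i < 0 || i >= g.nx) break; }
    else if (ty <= tz)        { j += sj; ty += dty; if (j < 0 || j >= g.ny) break; }
    else                      { k += sk; tz += dtz; if (k < 0 || k >= g.nz) break; }
    if (cell_exit > t1 + g.cell) break;
  }
  if (best_f < 0) return false;
  t_hit = best; f_hit = best_f;
  return true;
}

// first-hit distances for arbitrary rays (utility; also used by phantoms)
// [[Rcpp::export(name = ".cpp_ray_mesh_hits")]]
NumericVector cpp_ray_mesh_hits(NumericMatrix O, NumericMatrix D,
                                NumericMatrix V, IntegerMatrix F) {
  std::vector<Vec3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = {V(i, 0), V(i, 1), V(i, 2)};
  FaceGrid g = build_grid(verts, F);
  int nr = O.nrow();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    Vec3 o = {O(r, 0), O(r, 1), O(r, 2)};
    Vec3 d = {D(r, 0), D(r, 1), D(r, 2)};
    double n = vnorm(d);
    d = vscale(d, 1.0 / n);
    double t; int f;
    out[r] = grid_ray_first_hit(g, verts, F, o, d, -1, 1e-9, t, f) ? t : NA_REAL;
  }
  return out;
}

// Shape-diameter local thickness per face: rays in a cone around the inward
// normal, hit lengths corrected by 1/cos(angle) and reduced by the median.
// Only hits exiting through a front face (ray . hit-normal > 0) count.
// `probe` selects the (1-based) faces to measure; others return NA.
// [[Rcpp::export(name = ".cpp_face_thickness")]]
NumericVector cpp_face_thickness(NumericMatrix V, IntegerMatrix F,
                                 IntegerVector probe,
                                 int n_rays, double cone_half_deg, int seed) {
  const int nf = F.nrow();
  std::vector<Vec3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = {V(i, 0), V(i, 1), V(i, 2)};
  FaceGrid grid = build_grid(verts, F);
  std::vector<Vec3> nrm(nf), cen(nf);
  double mean_edge = 0;
  for (int f = 0; f < nf; ++f) {
    const Vec3 &a = verts[F(f, 0) - 1], &b = verts[F(f, 1) - 1], &c = verts[F(f, 2) - 1];
    Vec3 n = vcross(vsub(b, a), vsub(c, a));
    double ln = vnorm(n);
    nrm[f] = ln > 0 ? vscale(n, 1.0 / ln) : Vec3{0, 0, 1};
    cen[f] = vscale(vadd(a, vadd(b, c)), 1.0 / 3.0);
    mean_edge += vnorm(vsub(b, a));
  }
  mean_edge /= nf;
  const double cone = cone_half_deg * M_PI / 180.0;
  NumericVector out(nf, NA_REAL);
  std::vector<double> lens;
  lens.reserve(n_rays);
  // simple deterministic LCG so results are reproducible across platforms
  auto lcg = [](uint64_t &s) {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return (double)((s >> 11) & ((1ULL << 53) - 1)) / (double)(1ULL << 53);
  };
  for (int pi = 0; pi < probe.size(); ++pi) {
    int f = probe[pi] - 1;
    Vec3 in = vscale(nrm[f], -1.0);
    // orthonormal frame around the inward normal
    Vec3 up = std::fabs(in.z) < 0.9 ? Vec3{0, 0, 1} : Vec3{1, 0, 0};
    Vec3 u = vcross(in, up); u = vscale(u, 1.0 / vnorm(u));
    Vec3 w = vcross(in, u);
    Vec3 o = vadd(cen[f], vscale(in, 1e-4 * mean_edge));
    uint64_t s = (uint64_t)seed * 2654435761ULL + (uint64_t)f + 1;
    lens.clear();
    for (int r = 0; r < n_rays; ++r) {
      double th = (r == 0) ? 0.0 : cone * std::sqrt(lcg(s));
      double ph = 2 * M_PI * lcg(s);
      Vec3 d = vadd(vscale(in, std::cos(th)),
                    vadd(vscale(u, std::sin(th) * std::cos(ph)),
                         vscale(w, std::sin(th) * std::sin(ph))));
      double t; int fh;
      if (!grid_ray_first_hit(grid, verts, F, o, d, f, 1e-3 * mean_edge, t, fh)) continue;
      if (vdot(d, nrm[fh]) <= 0) continue;  // grazing/back hit, not an exit
      lens.push_back(t / std::max(std::cos(th), 0.5));
    }
    if (lens.empty()) { out[f] = NA_REAL; continue; }
    std::sort(lens.begin(), lens.end());
    size_t m = lens.size();
    out[f] = (m % 2 == 1) ? lens[m / 2] : 0.5 * (lens[m / 2 - 1] + lens[m / 2]);
  }
  return out;
}

// connected components of faces (shared-vertex connectivity, union-find)
// [[Rcpp::export(name = ".cpp_face_components")]]
IntegerVector cpp_face_components(IntegerMatrix F, int n_vertices) {
  const int nf = F.nrow();
  std::vector<int> parent(n_vertices + 1);
  for (int i = 0; i <= n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  for (int f = 0; f < nf; ++f) {
    unite(F(f, 0), F(f, 1));
    unite(F(f, 0), F(f, 2));
  }
  std::unordered_map<int, int> remap;
  IntegerVector out(nf);
  int next = 0;
  for (int f = 0; f < nf; ++f) {
    int root = find(F(f, 0));
    auto it = remap.find(root);
    if (it == remap.end()) { remap[root] = ++next; out[f] = next; }
    else out[f] = it->second;
  }
  return out;
}
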