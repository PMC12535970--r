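#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Minimal 3D quickhull: returns hull volume, hull surface area and the hull
// facets (one-based indices into the input points). Throws on degenerate
// (collinear/coplanar) input.

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // outward normal (unit) and plane offset
  std::vector<int> outside;
  bool alive;
};

struct Hull {
  const double* P;
  int n;
  std::vector<Face> faces;
  double eps;

  double px(int i) const { return P[i]; }
  double py(int i) const { return P[i + n]; }
  double pz(int i) const { return P[i + 2 * n]; }

  void plane(Face& f) {
    double ux = px(f.b) - px(f.a), uy = py(f.b) - py(f.a), uz = pz(f.b) - pz(f.a);
    double vx = px(f.c) - px(f.a), vy = py(f.c) - py(f.a), vz = pz(f.c) - pz(f.a);
    f.nx = uy * vz - uz * vy;
    f.ny = uz * vx - ux * vz;
    f.nz = ux * vy - uy * vx;
    double len = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (len > 0) { f.nx /= len; f.ny /= len; f.nz /= len; }
    f.off = f.nx * px(f.a) + f.ny * py(f.a) + f.nz * pz(f.a);
  }

  double dist(const Face& f, int p) const {
    return f.nx * px(p) + f.ny * py(p) + f.nz * pz(p) - f.off;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("degenerate hull: fewer than 4 points");
  Hull H;
  H.P = REAL(pts);
  H.n = n;
  // scale for tolerance
  double scale = 0;
  for (int k = 0; k < 3; ++k) {
    double mn = pts(0, k), mx = pts(0, k);
    for (int i = 1; i < n; ++i) { mn = std::min(mn, pts(i, k)); mx = std::max(mx, pts(i, k)); }
    scale = std::max(scale, mx - mn);
  }
  if (scale <= 0) stop("degenerate hull: all points identical");
  H.eps = 1e-10 * scale;

  // initial simplex: farthest pair among axis extremes, then line, then plane
  std::vector<int> extremes;
  for (int k = 0; k < 3; ++k) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (pts(i, k) < pts(imin, k)) imin = i;
      if (pts(i, k) > pts(imax, k)) imax = i;
    }
    extremes.push_back(imin); extremes.push_back(imax);
  }
  int i0 = 0, i1 = 1;
  double best = -1;
  for (size_t a = 0; a < extremes.size(); ++a)
    for (size_t b = a + 1; b < extremes.size(); ++b) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double dd = pts(extremes[a], k) - pts(extremes[b], k);
        d2 += dd * dd;
      }
      if (d2 > best) { best = d2; i0 = extremes[a]; i1 = extremes[b]; }
    }
  if (best <= H.eps * H.eps) stop("degenerate hull: all points identical");
  // farthest from the line i0-i1
  int i2 = -1; best = -1;
  double lx = pts(i1, 0) - pts(i0, 0), ly = pts(i1, 1) - pts(i0, 1), lz = pts(i1, 2) - pts(i0, 2);
  double ll = lx * lx + ly * ly + lz * lz;
  for (int i = 0; i < n; ++i) {
    double wx = pts(i, 0) - pts(i0, 0), wy = pts(i, 1) - pts(i0, 1), wz = pts(i, 2) - pts(i0, 2);
    double t = (wx * lx + wy * ly + wz * lz) / ll;
    double dx = wx - t * lx, dy = wy - t * ly, dz = wz - t * lz;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (best <= H.eps * H.eps) stop("degenerate hull: points are collinear");
  // farthest from plane i0,i1,i2
  double ux = pts(i1,0)-pts(i0,0), uy = pts(i1,1)-pts(i0,1), uz = pts(i1,2)-pts(i0,2);
  double vx = pts(i2,0)-pts(i0,0), vy = pts(i2,1)-pts(i0,1), vz = pts(i2,2)-pts(i0,2);
  double nx = uy*vz-uz*vy, ny = uz*vx-ux*vz, nz = ux*vy-uy*vx;
  double nl = std::sqrt(nx*nx+ny*ny+nz*nz);
  nx/=nl; ny/=nl; nz/=nl;
  int i3 = -1; best = -1; double sgn = 0;
  for (int i = 0; i < n; ++i) {
    double d = nx*(pts(i,0)-pts(i0,0)) + ny*(pts(i,1)-pts(i0,1)) + nz*(pts(i,2)-pts(i0,2));
    if (std::fabs(d) > best) { best = std::fabs(d); i3 = i; sgn = d; }
  }
  if (best <= H.eps) stop("degenerate hull: points are coplanar");
  if (sgn > 0) std::swap(i1, i2); // ensure i3 is below plane (i0,i1,i2)

  auto add_face = [&](int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    H.plane(f);
    H.faces.push_back(f);
    return (int)H.faces.size() - 1;
  };
  add_face(i0, i1, i2);
  add_face(i0, i2, i3);
  add_face(i2, i1, i3);
  add_face(i1, i0, i3);

  // assign points to faces
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : H.faces) {
      if (H.dist(f, i) > H.eps) { f.outside.push_back(i); break; }
    }
  }

  while (true) {
    int fi = -1;
    for (size_t i = 0; i < H.faces.size(); ++i)
      if (H.faces[i].alive && !H.faces[i].outside.empty()) { fi = (int)i; break; }
    if (fi < 0) break;
    // farthest point of that face
    Face& f0 = H.faces[fi];
    int p = f0.outside[0];
    double dmax = H.dist(f0, p);
    for (int q : f0.outside) {
      double d = H.dist(f0, q);
      if (d > dmax) { dmax = d; p = q; }
    }
    // visible faces
    std::vector<int> visible;
    std::vector<int> orphan;
    for (size_t i = 0; i < H.faces.size(); ++i) {
      Face& f = H.faces[i];
      if (!f.alive) continue;
      if (H.dist(f, p) > H.eps) {
        visible.push_back((int)i);
        for (int q : f.outside) if (q != p) orphan.push_back(q);
        f.alive = false;
        f.outside.clear();
      }
    }
    // horizon: directed edges of visible faces whose twin is not visible
    std::set<std::pair<int,int>> vis_edges;
    for (int vi : visible) {
      Face& f = H.faces[vi];
      vis_edges.insert({f.a, f.b});
      vis_edges.insert({f.b, f.c});
      vis_edges.insert({f.c, f.a});
    }
    std::vector<std::pair<int,int>> horizon;
    for (auto& e : vis_edges)
      if (!vis_edges.count({e.second, e.first})) horizon.push_back(e);
    // new faces from horizon to p
    std::vector<int> newf;
    for (auto& e : horizon) newf.push_back(add_face(e.first, e.second, p));
    // redistribute orphans
    for (int q : orphan) {
      for (int nf : newf) {
        Face& f = H.faces[nf];
        if (H.dist(f, q) > H.eps) { f.outside.push_back(q); break; }
      }
    }
  }

  // volume and area from alive faces (reference: centroid of hull vertices)
  std::set<int> hv;
  for (auto& f : H.faces) if (f.alive) { hv.insert(f.a); hv.insert(f.b); hv.insert(f.c); }
  double cx = 0, cy = 0, cz = 0;
  for (int i : hv) { cx += pts(i,0); cy += pts(i,1); cz += pts(i,2); }
  cx /= hv.size(); cy /= hv.size(); cz /= hv.size();
  double vol = 0, area = 0;
  std::vector<int> fa, fb, fc;
  for (auto& f : H.faces) {
    if (!f.alive) continue;
    double ax = pts(f.a,0)-cx, ay = pts(f.a,1)-cy, az = pts(f.a,2)-cz;
    double bx = pts(f.b,0)-cx, by = pts(f.b,1)-cy, bz = pts(f.b,2)-cz;
    double ox = pts(f.c,0)-cx, oy = pts(f.c,1)-cy, oz = pts(f.c,2)-cz;
    vol += (ax*(by*oz-bz*oy) - ay*(bx*oz-bz*ox) + az*(bx*oy-by*ox)) / 6.0;
    double ux2 = pts(f.b,0)-pts(f.a,0), uy2 = pts(f.b,1)-pts(f.a,1), uz2 = pts(f.b,2)-pts(f.a,2);
    double vx2 = pts(f.c,0)-pts(f.a,0), vy2 = pts(f.c,1)-pts(f.a,1), vz2 = pts(f.c,2)-pts(f.a,2);
    double qx = uy2*vz2-uz2*vy2, qy = uz2*vx2-ux2*vz2, qz = ux2*vy2-uy2*vx2;
    area += 0.5 * std::sqrt(qx*qx+qy*qy+qz*qz);
    fa.push_back(f.a + 1); fb.push_back(f.b + 1); fc.push_back(f.c + 1);
  }
  IntegerMatrix faces(fa.size(), 3);
  for (size_t i = 0; i < fa.size(); ++i) { faces(i,0) = fa[i]; faces(i,1) = fb[i]; faces(i,2) = fc[i]; }
  return List::create(_["volume"] = std::fabs(vol), _["area"] = area, _["faces"] = faces);
}
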