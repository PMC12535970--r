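#include <Rcpp.h>
#include <queue>
#include <functional>
#include <algorithm>
#include <map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// linear index helpers: column-major, dims = (nx, ny, nz), 0-based
static inline int lin(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// ---- 1D squared distance transform (Felzenszwalb & Huttenlocher) ----
static void dt1d(std::vector<double>& f, std::vector<double>& out,
                 std::vector<int>& v, std::vector<double>& zbuf, int n) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -1e30; zbuf[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = q - v[k];
    out[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the
// nearest TRUE voxel of `mask`.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : 1e30;
  int nmax = std::max(d[0], std::max(d[1], d[2]));
  std::vector<double> f(nmax), out(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y) {
      for (int x = 0; x < d[0]; ++x) f[x] = D[lin(x, y, z, d)];
      dt1d(f, out, v, zbuf, d[0]);
      for (int x = 0; x < d[0]; ++x) D[lin(x, y, z, d)] = out[x];
    }
  // y pass
  for (int z = 0; z < d[2]; ++z)
    for (int x = 0; x < d[0]; ++x) {
      for (int y = 0; y < d[1]; ++y) f[y] = D[lin(x, y, z, d)];
      dt1d(f, out, v, zbuf, d[1]);
      for (int y = 0; y < d[1]; ++y) D[lin(x, y, z, d)] = out[y];
    }
  // z pass
  for (int y = 0; y < d[1]; ++y)
    for (int x = 0; x < d[0]; ++x) {
      for (int z = 0; z < d[2]; ++z) f[z] = D[lin(x, y, z, d)];
      dt1d(f, out, v, zbuf, d[2]);
      for (int z = 0; z < d[2]; ++z) D[lin(x, y, z, d)] = out[z];
    }
  return D;
}

// 6-connected flood fill of the complement of `occ`, seeded from every
// non-occupied voxel on the grid boundary. Returns exterior mask.
// [[Rcpp::export]]
LogicalVector cpp_flood_exterior(LogicalVector occ, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector ext(n, false);
  std::queue<int> q;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        if (x == 0 || y == 0 || z == 0 ||
            x == d[0] - 1 || y == d[1] - 1 || z == d[2] - 1) {
          int i = lin(x, y, z, d);
          if (!occ[i] && !ext[i]) { ext[i] = true; q.push(i); }
        }
      }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int x = i % d[0], y = (i / d[0]) % d[1], z = i / (d[0] * d[1]);
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2]) continue;
      int j = lin(xx, yy, zz, d);
      if (!occ[j] && !ext[j]) { ext[j] = true; q.push(j); }
    }
  }
  return ext;
}

// Rasterize triangles into a voxel grid: barycentric surface sampling at
// spacing <= pitch/2, marking the voxel containing each sample.
// V is n x 3 (world units), F is m x 3 one-based vertex indices.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tris(NumericMatrix V, IntegerMatrix F,
                                 NumericVector origin, double pitch,
                                 IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector occ(n, false);
  double step = pitch * 0.5;
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double e1 = 0, e2 = 0, e3 = 0;
    for (int k = 0; k < 3; ++k) {
      double ab = V(b, k) - V(a, k), ac = V(c, k) - V(a, k), bc = V(c, k) - V(b, k);
      e1 += ab * ab; e2 += ac * ac; e3 += bc * bc;
    }
    double emax = std::sqrt(std::max(e1, std::max(e2, e3)));
    int ns = (int)std::ceil(emax / step);
    if (ns < 1) ns = 1;
    for (int i = 0; i <= ns; ++i) {
      for (int j = 0; j <= ns - i; ++j) {
        double u = (double)i / ns, v = (double)j / ns, w = 1.0 - u - v;
        double px = w * V(a, 0) + u * V(b, 0) + v * V(c, 0);
        double py = w * V(a, 1) + u * V(b, 1) + v * V(c, 1);
        double pz = w * V(a, 2) + u * V(b, 2) + v * V(c, 2);
        int xi = (int)std::floor((px - origin[0]) / pitch + 0.5);
        int yi = (int)std::floor((py - origin[1]) / pitch + 0.5);
        int zi = (int)std::floor((pz - origin[2]) / pitch + 0.5);
        if (xi < 0 || yi < 0 || zi < 0 || xi >= d[0] || yi >= d[1] || zi >= d[2]) continue;
        occ[lin(xi, yi, zi, d)] = true;
      }
    }
  }
  return occ;
}

// 6-connected component labels of TRUE voxels (0 for background).
// [[Rcpp::export]]
IntegerVector cpp_label_voxels(LogicalVector occ, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  int cur = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur; q.push((int)s);
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int x = i % d[0], y = (i / d[0]) % d[1], z = i / (d[0] * d[1]);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2]) continue;
        int j = lin(xx, yy, zz, d);
        if (occ[j] && !lab[j]) { lab[j] = cur; q.push(j); }
      }
    }
  }
  return lab;
}

// ---- marching tetrahedra ------------------------------------------------
// Extracts the iso-surface `field == iso` (field sampled at voxel centres,
// negative inside). Each grid cube is split into 6 tetrahedra sharing the
// 0-6 body diagonal. Triangle winding is fixed per-triangle so the normal
// points along the field gradient (outward for a signed distance field).

struct MTState {
  std::map<std::pair<int64_t, int64_t>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

static int mt_vertex(MTState& st, int64_t i1, int64_t i2, double f1, double f2,
                     double iso, const double* p1, const double* p2) {
  if (i1 > i2) { std::swap(i1, i2); std::swap(f1, f2); const double* t = p1; p1 = p2; p2 = t; }
  auto key = std::make_pair(i1, i2);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double denom = f2 - f1;
  double t = (std::fabs(denom) < 1e-12) ? 0.5 : (iso - f1) / denom;
  if (t < 0) t = 0; if (t > 1) t = 1;
  st.vx.push_back(p1[0] + t * (p2[0] - p1[0]));
  st.vy.push_back(p1[1] + t * (p2[1] - p1[1]));
  st.vz.push_back(p1[2] + t * (p2[2] - p1[2]));
  int id = (int)st.vx.size() - 1;
  st.edge_vertex[key] = id;
  return id;
}

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, double pitch, double iso) {
  int d[3] = {dims[0], dims[1], dims[2]};
  MTState st;
  // cube corner offsets
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing diagonal 0-6
  const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double P[8][3]; double Fv[8]; int64_t I[8];
  for (int z = 0; z < d[2] - 1; ++z)
    for (int y = 0; y < d[1] - 1; ++y)
      for (int x = 0; x < d[0] - 1; ++x) {
        bool anyin = false, anyout = false;
        for (int k = 0; k < 8; ++k) {
          int xx = x + co[k][0], yy = y + co[k][1], zz = z + co[k][2];
          I[k] = lin(xx, yy, zz, d);
          Fv[k] = field[I[k]];
          P[k][0] = origin[0] + xx * pitch;
          P[k][1] = origin[1] + yy * pitch;
          P[k][2] = origin[2] + zz * pitch;
          if (Fv[k] < iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4];
          for (int k = 0; k < 4; ++k) vi[k] = tets[t][k];
          int code = 0;
          for (int k = 0; k < 4; ++k) if (Fv[vi[k]] < iso) code |= (1 << k);
          if (code == 0 || code == 15) continue;
          // inside/outside split
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (Fv[vi[k]] < iso) ins[ni++] = vi[k]; else outs[no++] = vi[k];
          }
          auto mkv = [&](int a, int b) {
            return mt_vertex(st, I[a], I[b], Fv[a], Fv[b], iso, P[a], P[b]);
          };
          // emit triangle with winding fixed by gradient check afterwards
          auto emit = [&](int a, int b, int c) {
            // orient so normal points from inside to outside: use the mean
            // inside point as reference; normal must point away from it.
            double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
            double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
            double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
            double nx = uy * wz - uz * wy;
            double ny = uz * wx - ux * wz;
            double nz = ux * wy - uy * wx;
            // reference inside point: centroid of inside corners
            double rx = 0, ry = 0, rz = 0;
            for (int k = 0; k < ni; ++k) { rx += P[ins[k]][0]; ry += P[ins[k]][1]; rz += P[ins[k]][2]; }
            rx /= ni; ry /= ni; rz /= ni;
            double dot = nx * (ax - rx) + ny * (ay - ry) + nz * (az - rz);
            if (dot >= 0) { st.fa.push_back(a); st.fb.push_back(b); st.fc.push_back(c); }
            else { st.fa.push_back(a); st.fb.push_back(c); st.fc.push_back(b); }
          };
          if (ni == 1) {
            int p = ins[0];
            emit(mkv(p, outs[0]), mkv(p, outs[1]), mkv(p, outs[2]));
          } else if (ni == 3) {
            int p = outs[0];
            emit(mkv(ins[0], p), mkv(ins[1], p), mkv(ins[2], p));
          } else { // ni == 2: quad -> two triangles
            int a0 = ins[0], a1 = ins[1], b0 = outs[0], b1 = outs[1];
            int v00 = mkv(a0, b0), v01 = mkv(a0, b1), v10 = mkv(a1, b0), v11 = mkv(a1, b1);
            emit(v00, v01, v11);
            emit(v00, v11, v10);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i]; }
  for (int i = 0; i < nf; ++i) { Fc(i, 0) = st.fa[i] + 1; Fc(i, 1) = st.fb[i] + 1; Fc(i, 2) = st.fc[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---- 0-dimensional superlevel-set persistence ----------------------------
// Union-find sweep of vertices in decreasing f. A component is born at its
// maximum vertex; on merge the component with the smaller birth value dies
// (elder rule; ties broken so the lower-index birth vertex survives).
// Returns a matrix with columns birth, death, essential (0/1), birth_vertex.
// [[Rcpp::export]]
NumericMatrix cpp_persistence(NumericVector f, IntegerMatrix edges) {
  int n = f.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (f[a] != f[b]) return f[a] > f[b];
    return a < b;
  });
  std::vector<int> rank_of(n);
  for (int i = 0; i < n; ++i) rank_of[ord[i]] = i;
  // adjacency
  std::vector<int> deg(n, 0);
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) { deg[edges(e, 0) - 1]++; deg[edges(e, 1) - 1]++; }
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(off[n]);
  std::vector<int> pos(n, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[off[a] + pos[a]++] = b;
    adj[off[b] + pos[b]++] = a;
  }
  std::vector<int> parent(n, -1), birth(n, -1); // birth vertex of root's comp
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<double> bb, dd; std::vector<int> bv;
  for (int r = 0; r < n; ++r) {
    int v = ord[r];
    parent[v] = v; birth[v] = v;
    for (int k = off[v]; k < off[v + 1]; ++k) {
      int u = adj[k];
      if (rank_of[u] > r) continue; // not yet active
      int ru = find(u), rv = find(v);
      if (ru == rv) continue;
      int bu = birth[ru], bvx = birth[rv];
      // elder: larger birth f, tie -> lower birth vertex index
      bool u_elder = (f[bu] > f[bvx]) || (f[bu] == f[bvx] && bu < bvx);
      int elder = u_elder ? ru : rv;
      int young = u_elder ? rv : ru;
      int yb = birth[young];
      // record death of younger at current level f[v]
      bb.push_back(f[yb]); dd.push_back(f[v]); bv.push_back(yb);
      parent[young] = elder;
    }
  }
  // essential bars: one per connected component, death 0
  std::vector<bool> seen(n, false);
  std::vector<int> ess;
  for (int i = 0; i < n; ++i) {
    int rt = find(i);
    if (!seen[rt]) { seen[rt] = true; ess.push_back(birth[rt]); }
  }
  int nb = (int)bb.size(), ne = (int)ess.size();
  NumericMatrix out(nb + ne, 4);
  int r = 0;
  for (int i = 0; i < nb; ++i, ++r) {
    out(r, 0) = bb[i]; out(r, 1) = dd[i]; out(r, 2) = 0; out(r, 3) = bv[i] + 1;
  }
  for (int i = 0; i < ne; ++i, ++r) {
    out(r, 0) = f[ess[i]]; out(r, 1) = 0.0; out(r, 2) = 1; out(r, 3) = ess[i] + 1;
  }
  return out;
}

// ---- parity fill ---------------------------------------------------------
// Marks voxels whose centre lies inside a watertight mesh, by casting an
// x-direction ray through every (y,z) grid column and counting triangle
// crossings below each voxel centre. Column positions are jittered by a
// fixed sub-voxel offset to avoid edge/vertex ties.
// [[Rcpp::export]]
LogicalVector cpp_parity_fill(NumericMatrix V, IntegerMatrix F,
                              NumericVector origin, double pitch,
                              IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector occ(n, false);
  double jy = pitch * 1.2345e-3, jz = pitch * 2.3457e-3;
  std::vector<std::vector<double>> cross((size_t)d[1] * d[2]);
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double y1 = V(a, 1), z1 = V(a, 2), y2 = V(b, 1), z2 = V(b, 2), y3 = V(c, 1), z3 = V(c, 2);
    double x1 = V(a, 0), x2 = V(b, 0), x3 = V(c, 0);
    double den = (y2 - y1) * (z3 - z1) - (y3 - y1) * (z2 - z1);
    if (std::fabs(den) < 1e-14) continue; // ray-parallel triangle
    double ymin = std::min(y1, std::min(y2, y3)), ymax = std::max(y1, std::max(y2, y3));
    double zmin = std::min(z1, std::min(z2, z3)), zmax = std::max(z1, std::max(z2, z3));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1] - jy) / pitch - 0.25));
    int j1 = std::min(d[1] - 1, (int)std::floor((ymax - origin[1] - jy) / pitch + 0.25));
    int k0 = std::max(0, (int)std::ceil((zmin - origin[2] - jz) / pitch - 0.25));
    int k1 = std::min(d[2] - 1, (int)std::floor((zmax - origin[2] - jz) / pitch + 0.25));
    for (int k = k0; k <= k1; ++k) {
      double zc = origin[2] + k * pitch + jz;
      for (int j = j0; j <= j1; ++j) {
        double yc = origin[1] + j * pitch + jy;
        double l1 = ((y2 - yc) * (z3 - zc) - (y3 - yc) * (z2 - zc)) / den;
        double l2 = ((y3 - yc) * (z1 - zc) - (y1 - yc) * (z3 - zc)) / den;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        double xh = l1 * x1 + l2 * x2 + l3 * x3;
        cross[(size_t)j + (size_t)d[1] * k].push_back(xh);
      }
    }
  }
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j) {
      std::vector<double>& xs = cross[(size_t)j + (size_t)d[1] * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // parity: voxel centre inside if an odd number of crossings precede it
      size_t ci = 0;
      int parity = 0;
      for (int i = 0; i < d[0]; ++i) {
        double xc = origin[0] + i * pitch;
        while (ci < xs.size() && xs[ci] <= xc) { parity ^= 1; ++ci; }
        if (parity) occ[lin(i, j, k, d)] = true;
      }
    }
  return occ;
}
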