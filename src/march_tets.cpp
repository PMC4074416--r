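#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction at level 0.5 from a 0/1 grid by marching
// tetrahedra on the Freudenthal 6-tetrahedron cube decomposition. The
// decomposition is translation-invariant (cube faces are always split
// along the min-corner -> max-corner diagonal), so neighbouring cells
// triangulate shared faces identically and the surface of a closed mask
// is watertight. Surface vertices sit at edge midpoints (linear
// interpolation of 0/1 data at iso 0.5); they are welded via the grid
// edge they lie on, so every interior edge is shared by exactly 2 faces.
// Triangles are oriented with outward normals (away from the inside
// region), making divergence-theorem volumes signed consistently.

struct MeshAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> f;
  std::unordered_map<uint64_t, int> edge_vertex;
};

static int edge_vertex_id(MeshAccum& m, uint64_t a, uint64_t b,
                          const double* pa, const double* pb) {
  if (a > b) { std::swap(a, b); const double* t = pa; pa = pb; pb = t; }
  uint64_t key = a * 0x100000000ULL ^ b;
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  int id = (int)m.vx.size();
  m.vx.push_back(0.5 * (pa[0] + pb[0]));
  m.vy.push_back(0.5 * (pa[1] + pb[1]));
  m.vz.push_back(0.5 * (pa[2] + pb[2]));
  m.edge_vertex.emplace(key, id);
  return id;
}

static void emit_tri(MeshAccum& m, int a, int b, int c,
                     const double* ref) {
  // orient so the normal points away from the inside reference point
  double ax = m.vx[a], ay = m.vy[a], az = m.vz[a];
  double ux = m.vx[b] - ax, uy = m.vy[b] - ay, uz = m.vz[b] - az;
  double wx = m.vx[c] - ax, wy = m.vy[c] - ay, wz = m.vz[c] - az;
  double nxv = uy * wz - uz * wy;
  double nyv = uz * wx - ux * wz;
  double nzv = ux * wy - uy * wx;
  double cx = (ax + m.vx[b] + m.vx[c]) / 3.0 - ref[0];
  double cy = (ay + m.vy[b] + m.vy[c]) / 3.0 - ref[1];
  double cz = (az + m.vz[b] + m.vz[c]) / 3.0 - ref[2];
  if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(b, c);
  m.f.push_back(a); m.f.push_back(b); m.f.push_back(c);
}

// corner bit order: bit0 = +x, bit1 = +y, bit2 = +z
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(LogicalVector mask, IntegerVector dims,
                NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  MeshAccum m;

  double cpos[8][3];
  uint64_t cid[8];
  bool cin[8];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int inside_count = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          uint64_t lin = ci + (uint64_t)nx * (cj + (uint64_t)ny * ck);
          cid[c] = lin;
          cin[c] = mask[lin];
          inside_count += cin[c];
          cpos[c][0] = origin[0] + ci * spacing[0];
          cpos[c][1] = origin[1] + cj * spacing[1];
          cpos[c][2] = origin[2] + ck * spacing[2];
        }
        if (inside_count == 0 || inside_count == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            if (cin[T[v]]) ins[ni++] = T[v]; else outs[no++] = T[v];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            int others[3], n2 = 0;
            for (int v = 0; v < 4; ++v) if (T[v] != apex) others[n2++] = T[v];
            int e0 = edge_vertex_id(m, cid[apex], cid[others[0]],
                                    cpos[apex], cpos[others[0]]);
            int e1 = edge_vertex_id(m, cid[apex], cid[others[1]],
                                    cpos[apex], cpos[others[1]]);
            int e2 = edge_vertex_id(m, cid[apex], cid[others[2]],
                                    cpos[apex], cpos[others[2]]);
            double ref[3];
            if (ni == 1) {
              ref[0] = cpos[apex][0]; ref[1] = cpos[apex][1]; ref[2] = cpos[apex][2];
            } else {  // reference = centroid of the three inside corners
              ref[0] = (cpos[others[0]][0] + cpos[others[1]][0] + cpos[others[2]][0]) / 3.0;
              ref[1] = (cpos[others[0]][1] + cpos[others[1]][1] + cpos[others[2]][1]) / 3.0;
              ref[2] = (cpos[others[0]][2] + cpos[others[1]][2] + cpos[others[2]][2]) / 3.0;
            }
            emit_tri(m, e0, e1, e2, ref);
          } else {  // 2 in, 2 out: quad split into two triangles
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int eac = edge_vertex_id(m, cid[a], cid[c], cpos[a], cpos[c]);
            int ead = edge_vertex_id(m, cid[a], cid[d], cpos[a], cpos[d]);
            int ebd = edge_vertex_id(m, cid[b], cid[d], cpos[b], cpos[d]);
            int ebc = edge_vertex_id(m, cid[b], cid[c], cpos[b], cpos[c]);
            double ref[3] = {0.5 * (cpos[a][0] + cpos[b][0]),
                             0.5 * (cpos[a][1] + cpos[b][1]),
                             0.5 * (cpos[a][2] + cpos[b][2])};
            emit_tri(m, eac, ead, ebd, ref);
            emit_tri(m, eac, ebd, ebc, ref);
          }
        }
      }

  int nv = (int)m.vx.size(), nf = (int)m.f.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = m.vx[v]; verts(v, 1) = m.vy[v]; verts(v, 2) = m.vz[v];
  }
  IntegerMatrix faces(nf, 3);
  for (int t = 0; t < nf; ++t) {
    faces(t, 0) = m.f[3 * t] + 1;      // 1-based for R
    faces(t, 1) = m.f[3 * t + 1] + 1;
    faces(t, 2) = m.f[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Exact maximum pairwise Euclidean distance among points (n x 3, mm).
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix pts) {
  double best = 0.0;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
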