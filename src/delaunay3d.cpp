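// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson) used as the
// backbone of the alpha-complex crown model, plus tetrahedron-based voxel
// membership tests.
//
// Robustness strategy: the triangulation runs on coordinates perturbed by a
// deterministic, index-hashed jitter (default 3e-5 x bounding-box span),
// which resolves cospherical/coplanar degeneracies and keeps every insphere
// determinant far enough from zero for doubles to decide consistently; all
// reported metrics (circumradius, volume) are computed from the ORIGINAL
// coordinates, so degenerate slivers contribute ~zero volume and exact
// inputs give exact volumes.  The jitter and the super-tetrahedron distance
// are balanced so that sliver circumspheres (radius ~ span/jitter) stay
// well inside the super vertices while predicates retain precision; an
// inconsistent cavity triggers a deterministic retry with larger jitter.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];     // vertex ids
  int nb[4];    // neighbor opposite local vertex i, -1 if none
  double cc[3]; // circumcenter (jittered coords)
  double r2;    // squared circumradius (jittered coords)
  bool alive;
};

inline double orient3d(const double* a, const double* b, const double* c,
                       const double* d) {
  const double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  const double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  const double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// circumcenter/radius^2 of tetra (a,b,c,d); returns false when degenerate
inline bool circumsphere(const double* a, const double* b, const double* c,
                         const double* d, double* cc, double& r2,
                         double cond_tol = 1e-14) {
  double B[3], C[3], D[3];
  for (int i = 0; i < 3; ++i) {
    B[i] = b[i] - a[i];
    C[i] = c[i] - a[i];
    D[i] = d[i] - a[i];
  }
  const double rb = 0.5 * (B[0] * B[0] + B[1] * B[1] + B[2] * B[2]);
  const double rc = 0.5 * (C[0] * C[0] + C[1] * C[1] + C[2] * C[2]);
  const double rd = 0.5 * (D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
  const double det = B[0] * (C[1] * D[2] - C[2] * D[1]) -
                     B[1] * (C[0] * D[2] - C[2] * D[0]) +
                     B[2] * (C[0] * D[1] - C[1] * D[0]);
  const double scale = std::fabs(B[0]) + std::fabs(B[1]) + std::fabs(B[2]) +
                       std::fabs(C[0]) + std::fabs(C[1]) + std::fabs(C[2]) +
                       std::fabs(D[0]) + std::fabs(D[1]) + std::fabs(D[2]);
  if (std::fabs(det) <= cond_tol * scale * scale * scale) return false;
  double x[3];
  const double det1 = rb * (C[1] * D[2] - C[2] * D[1]) -
                      B[1] * (rc * D[2] - C[2] * rd) +
                      B[2] * (rc * D[1] - C[1] * rd);
  const double det2 = B[0] * (rc * D[2] - C[2] * rd) -
                      rb * (C[0] * D[2] - C[2] * D[0]) +
                      B[2] * (C[0] * rd - rc * D[0]);
  const double det3 = B[0] * (C[1] * rd - rc * D[1]) -
                      B[1] * (C[0] * rd - rc * D[0]) +
                      rb * (C[0] * D[1] - C[1] * D[0]);
  x[0] = det1 / det;
  x[1] = det2 / det;
  x[2] = det3 / det;
  cc[0] = a[0] + x[0];
  cc[1] = a[1] + x[1];
  cc[2] = a[2] + x[2];
  r2 = x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
  return true;
}

// insphere determinant (Shewchuk's formulation, double precision): for a
// positively oriented tetra (a,b,c,d), positive iff e lies inside the
// circumsphere.  The construction jitter keeps the determinant away from
// zero, so plain doubles decide consistently.
inline double insphere_det(const double* a, const double* b, const double* c,
                           const double* d, const double* e) {
  const double aex = a[0] - e[0], aey = a[1] - e[1], aez = a[2] - e[2];
  const double bex = b[0] - e[0], bey = b[1] - e[1], bez = b[2] - e[2];
  const double cex = c[0] - e[0], cey = c[1] - e[1], cez = c[2] - e[2];
  const double dex = d[0] - e[0], dey = d[1] - e[1], dez = d[2] - e[2];

  const double ab = aex * bey - bex * aey;
  const double bc = bex * cey - cex * bey;
  const double cd = cex * dey - dex * cey;
  const double da = dex * aey - aex * dey;
  const double ac = aex * cey - cex * aey;
  const double bd = bex * dey - dex * bey;

  const double abc = aez * bc - bez * ac + cez * ab;
  const double bcd = bez * cd - cez * bd + dez * bc;
  const double cda = cez * da + dez * ac + aez * cd;
  const double dab = dez * ab + aez * bd + bez * da;

  const double alift = aex * aex + aey * aey + aez * aez;
  const double blift = bex * bex + bey * bey + bez * bez;
  const double clift = cex * cex + cey * cey + cez * cez;
  const double dlift = dex * dex + dey * dey + dez * dez;

  return (dlift * abc - clift * dab) + (blift * cda - alift * bcd);
}

// deterministic jitter in [-0.5, 0.5) from a 64-bit mix of (index, axis)
inline double hash_unit(uint64_t i, uint64_t axis) {
  uint64_t x = i * 0x9E3779B97F4A7C15ULL + axis * 0xBF58476D1CE4E5B9ULL + 1ULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return (double)(x >> 11) / 9007199254740992.0 - 0.5;
}

struct Delaunay {
  std::vector<double> pts;  // jittered, 3 * nv (includes 4 super vertices)
  int n;                    // number of real points
  std::vector<Tet> tets;
  bool failed = false;      // cavity inconsistency: retry with more jitter

  const double* P(int i) const { return &pts[3 * i]; }

  bool in_sphere(const Tet& t, const double* p) const {
    // cached circumsphere as a conservative filter; near the boundary (or
    // for slivers, where the circumcenter is ill-conditioned) fall back to
    // the determinant predicate
    if (t.r2 >= 0) {
      const double dx = p[0] - t.cc[0], dy = p[1] - t.cc[1],
                   dz = p[2] - t.cc[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < t.r2 * (1.0 - 1e-6)) return true;
      if (d2 > t.r2 * (1.0 + 1e-6)) return false;
    }
    return insphere_det(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]), p) > 0;
  }

  int make_tet(int a, int b, int c, int d) {
    Tet t;
    if (orient3d(P(a), P(b), P(c), P(d)) < 0) std::swap(c, d);
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    t.alive = true;
    // cache the circumsphere only when it is well-conditioned; otherwise
    // conflict tests go straight to the determinant predicate (r2 = -1)
    if (!circumsphere(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]), t.cc, t.r2,
                      1e-6)) {
      t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
      t.r2 = -1.0;
    }
    tets.push_back(t);
    return (int)tets.size() - 1;
  }

  int find_conflict(const double* p) const {
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && in_sphere(tets[i], p)) return i;
    return -1;
  }

  void insert(int pid) {
    const double* p = P(pid);
    int seed = find_conflict(p);
    if (seed < 0) { failed = true; return; }

    // grow connected cavity of conflicting tets
    std::vector<int> cavity;
    std::unordered_set<int> in_cavity;
    std::vector<int> stack{seed};
    in_cavity.insert(seed);
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int u = tets[t].nb[f];
        if (u >= 0 && !in_cavity.count(u) && tets[u].alive &&
            in_sphere(tets[u], p)) {
          in_cavity.insert(u);
          stack.push_back(u);
        }
      }
    }

    // boundary faces: (three vertices, outside tet, outside tet's face index)
    struct BFace { int a, b, c, out; };
    std::vector<BFace> faces;
    for (int t : cavity) {
      for (int f = 0; f < 4; ++f) {
        int u = tets[t].nb[f];
        if (u < 0 || !in_cavity.count(u)) {
          BFace bf;
          int idx = 0;
          int vv[3];
          for (int j = 0; j < 4; ++j)
            if (j != f) vv[idx++] = tets[t].v[j];
          bf.a = vv[0]; bf.b = vv[1]; bf.c = vv[2];
          bf.out = u;
          faces.push_back(bf);
        }
      }
    }
    for (int t : cavity) tets[t].alive = false;

    // retriangulate: connect pid to each boundary face
    std::unordered_map<uint64_t, std::pair<int,int>> edge_map; // edge -> (tet, local face)
    edge_map.reserve(faces.size() * 3);
    std::vector<int> created;
    created.reserve(faces.size());
    for (const BFace& bf : faces) {
      int nt = make_tet(pid, bf.a, bf.b, bf.c);
      created.push_back(nt);
      // neighbor opposite pid is the outside tet
      int lp = -1;
      for (int j = 0; j < 4; ++j) if (tets[nt].v[j] == pid) { lp = j; break; }
      tets[nt].nb[lp] = bf.out;
      if (bf.out >= 0) {
        // fix back-pointer in outside tet: its face not containing pid's face verts
        for (int j = 0; j < 4; ++j) {
          int w = tets[bf.out].v[j];
          if (w != bf.a && w != bf.b && w != bf.c) {
            tets[bf.out].nb[j] = nt;
            break;
          }
        }
      }
      // internal adjacency via the three boundary edges
      int fv[3] = {bf.a, bf.b, bf.c};
      for (int e = 0; e < 3; ++e) {
        int x = fv[e], y = fv[(e + 1) % 3];
        if (x > y) std::swap(x, y);
        uint64_t key = ((uint64_t)(uint32_t)x << 32) | (uint32_t)y;
        // local index of the vertex opposite the shared face (pid, x, y):
        int z = fv[(e + 2) % 3];
        int lz = -1;
        for (int j = 0; j < 4; ++j) if (tets[nt].v[j] == z) { lz = j; break; }
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = {nt, lz};
        } else {
          tets[nt].nb[lz] = it->second.first;
          tets[it->second.first].nb[it->second.second] = nt;
          edge_map.erase(it);
        }
      }
    }
    // a consistent (star-shaped) cavity pairs every internal edge exactly
    // twice; anything left over means the predicates disagreed
    if (!edge_map.empty()) failed = true;
  }
};

} // namespace

// one triangulation attempt at a given jitter scale; failure (inconsistent
// cavity) is reported through D.failed
static bool build_triangulation(Delaunay& D, const NumericMatrix& coords,
                                double span, const double* lo,
                                const double* hi, double eps,
                                uint64_t salt, double super_rel) {
  const int n = coords.nrow();
  D.tets.clear();
  D.failed = false;
  D.n = n;
  D.pts.assign(3 * (n + 4), 0.0);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a)
      D.pts[3 * i + a] =
          coords(i, a) + eps * hash_unit((uint64_t)i + 1 + salt, a);

  // enclosing super tetrahedron; far enough away that even sliver
  // circumspheres (radius ~ span / jitter_rel) cannot reach its vertices
  const double cx = 0.5 * (lo[0] + hi[0]);
  const double cy = 0.5 * (lo[1] + hi[1]);
  const double cz = 0.5 * (lo[2] + hi[2]);
  const double M = super_rel * span;
  const double sv[4][3] = {{cx - 2.0 * M, cy - M, cz - M},
                           {cx + 2.0 * M, cy - M, cz - M},
                           {cx, cy + 2.0 * M, cz - M},
                           {cx, cy, cz + 2.0 * M}};
  for (int s = 0; s < 4; ++s)
    for (int a = 0; a < 3; ++a) D.pts[3 * (n + s) + a] = sv[s][a];
  D.make_tet(n, n + 1, n + 2, n + 3);

  // insert points in a spatially coherent order so conflict search from the
  // newest tetra terminates quickly
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int i, int j) {
    const double* a = &D.pts[3 * i];
    const double* b = &D.pts[3 * j];
    const double ka = a[0] + 0.7548776662 * a[1] + 0.5698402910 * a[2];
    const double kb = b[0] + 0.7548776662 * b[1] + 0.5698402910 * b[2];
    return ka < kb;
  });
  for (int i : order) {
    D.insert(i);
    if (D.failed) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix coords, double jitter_rel = 3e-5,
                    double super_rel = 1e4) {
  const int n = coords.nrow();
  if (n < 4) stop("need at least 4 points");

  // bounding box of original coords
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      if (coords(i, a) < lo[a]) lo[a] = coords(i, a);
      if (coords(i, a) > hi[a]) hi[a] = coords(i, a);
    }
  double span = 0.0;
  for (int a = 0; a < 3; ++a) span = std::max(span, hi[a] - lo[a]);
  if (span <= 0) stop("all points coincide");

  // deterministic retries with growing jitter if a cavity turns inconsistent
  Delaunay D;
  bool ok = false;
  double eps = jitter_rel * span;
  for (int attempt = 0; attempt < 5 && !ok; ++attempt) {
    ok = build_triangulation(D, coords, span, lo, hi, eps,
                             (uint64_t)attempt * 7919ULL, super_rel);
    eps *= 5.0;
  }
  if (!ok)
    stop("delaunay3d: triangulation failed on degenerate input");

  // collect real tetrahedra; compute metrics from the ORIGINAL coordinates
  std::vector<int> keep;
  for (int t = 0; t < (int)D.tets.size(); ++t) {
    if (!D.tets[t].alive) continue;
    bool real_tet = true;
    for (int j = 0; j < 4; ++j)
      if (D.tets[t].v[j] >= n) { real_tet = false; break; }
    if (real_tet) keep.push_back(t);
  }
  const int m = (int)keep.size();
  IntegerMatrix tv(m, 4);
  NumericVector circumr(m), vol(m);
  NumericMatrix ccout(m, 3);
  for (int r = 0; r < m; ++r) {
    const Tet& t = D.tets[keep[r]];
    double q[4][3];
    for (int j = 0; j < 4; ++j) {
      tv(r, j) = t.v[j] + 1;
      for (int a = 0; a < 3; ++a) q[j][a] = coords(t.v[j], a);
    }
    vol[r] = std::fabs(orient3d(q[0], q[1], q[2], q[3])) / 6.0;
    double cc[3], r2;
    if (circumsphere(q[0], q[1], q[2], q[3], cc, r2)) {
      circumr[r] = std::sqrt(r2);
      ccout(r, 0) = cc[0]; ccout(r, 1) = cc[1]; ccout(r, 2) = cc[2];
    } else {
      circumr[r] = R_PosInf;  // flat sliver from a degenerate configuration
      ccout(r, 0) = ccout(r, 1) = ccout(r, 2) = NA_REAL;
    }
  }
  return List::create(_["tetra"] = tv, _["circumradius"] = circumr,
                      _["volume"] = vol, _["circumcenter"] = ccout);
}

// Voxel centers inside any of the given tetrahedra (barycentric sign test
// with tolerance), returned as unique integer (i, j, k) triples.
// [[Rcpp::export(name = ".voxelize_tetra_cpp")]]
IntegerMatrix voxelize_tetra_cpp(NumericMatrix verts, IntegerMatrix tetra,
                                 NumericVector origin, double s,
                                 double tol = 1e-9) {
  std::unordered_set<uint64_t> seen;
  std::vector<int> out;
  const double x0 = origin[0], y0 = origin[1], z0 = origin[2];
  const int m = tetra.nrow();
  for (int t = 0; t < m; ++t) {
    double a[3], B[3][3];
    for (int c = 0; c < 3; ++c) a[c] = verts(tetra(t, 0) - 1, c);
    for (int j = 0; j < 3; ++j)
      for (int c = 0; c < 3; ++c)
        B[c][j] = verts(tetra(t, j + 1) - 1, c) - a[c];
    const double det =
        B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
        B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
        B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0]);
    if (std::fabs(det) < 1e-300) continue;
    // inverse of B
    double inv[3][3];
    inv[0][0] = (B[1][1] * B[2][2] - B[1][2] * B[2][1]) / det;
    inv[0][1] = (B[0][2] * B[2][1] - B[0][1] * B[2][2]) / det;
    inv[0][2] = (B[0][1] * B[1][2] - B[0][2] * B[1][1]) / det;
    inv[1][0] = (B[1][2] * B[2][0] - B[1][0] * B[2][2]) / det;
    inv[1][1] = (B[0][0] * B[2][2] - B[0][2] * B[2][0]) / det;
    inv[1][2] = (B[0][2] * B[1][0] - B[0][0] * B[1][2]) / det;
    inv[2][0] = (B[1][0] * B[2][1] - B[1][1] * B[2][0]) / det;
    inv[2][1] = (B[0][1] * B[2][0] - B[0][0] * B[2][1]) / det;
    inv[2][2] = (B[0][0] * B[1][1] - B[0][1] * B[1][0]) / det;

    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 4; ++j)
      for (int c = 0; c < 3; ++c) {
        const double v = verts(tetra(t, j) - 1, c);
        if (v < lo[c]) lo[c] = v;
        if (v > hi[c]) hi[c] = v;
      }
    const double o[3] = {x0, y0, z0};
    int ilo[3], ihi[3];
    for (int c = 0; c < 3; ++c) {
      ilo[c] = (int)std::floor((lo[c] - o[c]) / s - 0.5 - tol);
      ihi[c] = (int)std::ceil((hi[c] - o[c]) / s - 0.5 + tol);
    }
    for (int i = ilo[0]; i <= ihi[0]; ++i)
      for (int j = ilo[1]; j <= ihi[1]; ++j)
        for (int k = ilo[2]; k <= ihi[2]; ++k) {
          const double q[3] = {x0 + (i + 0.5) * s - a[0],
                               y0 + (j + 0.5) * s - a[1],
                               z0 + (k + 0.5) * s - a[2]};
          const double l1 = inv[0][0] * q[0] + inv[0][1] * q[1] + inv[0][2] * q[2];
          const double l2 = inv[1][0] * q[0] + inv[1][1] * q[1] + inv[1][2] * q[2];
          const double l3 = inv[2][0] * q[0] + inv[2][1] * q[1] + inv[2][2] * q[2];
          if (l1 >= -tol && l2 >= -tol && l3 >= -tol &&
              l1 + l2 + l3 <= 1.0 + tol) {
            uint64_t key = ((uint64_t)(uint32_t)(i + 1000000) * 4000037ULL +
                            (uint64_t)(uint32_t)(j + 1000000)) * 4000037ULL +
                           (uint64_t)(uint32_t)(k + 1000000);
            if (seen.insert(key).second) {
              out.push_back(i);
              out.push_back(j);
              out.push_back(k);
            }
          }
        }
  }
  const int nv = (int)out.size() / 3;
  IntegerMatrix res(nv, 3);
  for (int r = 0; r < nv; ++r) {
    res(r, 0) = out[3 * r];
    res(r, 1) = out[3 * r + 1];
    res(r, 2) = out[3 * r + 2];
  }
  return res;
}
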