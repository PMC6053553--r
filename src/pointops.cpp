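// Spatial-hash accelerated point-cloud primitives: mean k-nearest-neighbour
// distances (statistical outlier removal), greedy minimum-distance
// subsampling, and first-hit ray casting against sphere/cylinder/rectangle
// primitives for the scan simulator.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <queue>

using namespace Rcpp;

namespace {

inline uint64_t cell_key(int64_t i, int64_t j, int64_t k) {
  return ((uint64_t)(uint32_t)(i + 2000000000LL) * 73856093ULL) ^
         ((uint64_t)(uint32_t)(j + 2000000000LL) * 19349663ULL) ^
         ((uint64_t)(uint32_t)(k + 2000000000LL) * 83492791ULL);
}

struct Grid {
  double h;
  std::unordered_map<uint64_t, std::vector<int>> cells;
  const double* x; const double* y; const double* z;

  void build(const double* xx, const double* yy, const double* zz, int n,
             double hh) {
    x = xx; y = yy; z = zz; h = hh;
    cells.reserve(n * 2);
    for (int i = 0; i < n; ++i) add(i);
  }
  inline void cell_of(int i, int64_t& ci, int64_t& cj, int64_t& ck) const {
    ci = (int64_t)std::floor(x[i] / h);
    cj = (int64_t)std::floor(y[i] / h);
    ck = (int64_t)std::floor(z[i] / h);
  }
  void add(int i) {
    int64_t ci, cj, ck;
    cell_of(i, ci, cj, ck);
    cells[cell_key(ci, cj, ck)].push_back(i);
  }
};

} // namespace

// [[Rcpp::export(name = ".knn_mean_dist_cpp")]]
NumericVector knn_mean_dist_cpp(NumericVector x, NumericVector y,
                                NumericVector z, int k) {
  const int n = x.size();
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");

  // cell size targeting ~2 points per cell, bounded away from zero
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    lo[0] = std::min(lo[0], x[i]); hi[0] = std::max(hi[0], x[i]);
    lo[1] = std::min(lo[1], y[i]); hi[1] = std::max(hi[1], y[i]);
    lo[2] = std::min(lo[2], z[i]); hi[2] = std::max(hi[2], z[i]);
  }
  double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double h = span / std::max(1.0, std::cbrt((double)n / 2.0));

  Grid g;
  g.build(x.begin(), y.begin(), z.begin(), n, h);

  NumericVector out(n);
  std::vector<double> d2s;
  for (int i = 0; i < n; ++i) {
    int64_t ci, cj, ck;
    g.cell_of(i, ci, cj, ck);
    int ring = 1;
    for (;;) {
      d2s.clear();
      for (int64_t a = ci - ring; a <= ci + ring; ++a)
        for (int64_t b = cj - ring; b <= cj + ring; ++b)
          for (int64_t c = ck - ring; c <= ck + ring; ++c) {
            auto it = g.cells.find(cell_key(a, b, c));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
              d2s.push_back(dx * dx + dy * dy + dz * dz);
            }
          }
      if ((int)d2s.size() >= k) {
        std::nth_element(d2s.begin(), d2s.begin() + (k - 1), d2s.end());
        const double rk = std::sqrt(d2s[k - 1]);
        if (rk <= ring * h || ring * h >= span) {
          // the k-th neighbour is certainly inside the searched ring
          std::partial_sort(d2s.begin(), d2s.begin() + k, d2s.end());
          double acc = 0.0;
          for (int q = 0; q < k; ++q) acc += std::sqrt(d2s[q]);
          out[i] = acc / k;
          break;
        }
      }
      if (ring * h >= 2.0 * span && (int)d2s.size() >= k) {
        std::partial_sort(d2s.begin(), d2s.begin() + k, d2s.end());
        double acc = 0.0;
        for (int q = 0; q < k; ++q) acc += std::sqrt(d2s[q]);
        out[i] = acc / k;
        break;
      }
      ++ring;
    }
  }
  return out;
}

// greedy first-come subsampling: keep a point iff no previously kept point
// lies within min_dist (3D Euclidean); returns keep flags
// [[Rcpp::export(name = ".greedy_subsample_cpp")]]
LogicalVector greedy_subsample_cpp(NumericVector x, NumericVector y,
                                   NumericVector z, double min_dist) {
  const int n = x.size();
  LogicalVector keep(n);
  const double h = min_dist;
  const double d2min = min_dist * min_dist;
  std::unordered_map<uint64_t, std::vector<int>> cells;
  cells.reserve(n);
  for (int i = 0; i < n; ++i) {
    const int64_t ci = (int64_t)std::floor(x[i] / h);
    const int64_t cj = (int64_t)std::floor(y[i] / h);
    const int64_t ck = (int64_t)std::floor(z[i] / h);
    bool ok = true;
    for (int64_t a = ci - 1; a <= ci + 1 && ok; ++a)
      for (int64_t b = cj - 1; b <= cj + 1 && ok; ++b)
        for (int64_t c = ck - 1; c <= ck + 1 && ok; ++c) {
          auto it = cells.find(cell_key(a, b, c));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
            if (dx * dx + dy * dy + dz * dz < d2min) { ok = false; break; }
          }
        }
    keep[i] = ok;
    if (ok) cells[cell_key(ci, cj, ck)].push_back(i);
  }
  return keep;
}

// First-hit ray casting.  Primitive encoding, one row each:
//   type 0 sphere:    cx cy cz r  .  .  .  .  .  .
//   type 1 cylinder:  x0 y0 z0 x1 y1 z1 r  .  .  .   (finite, uncapped)
//   type 2 rectangle: px py pz ux uy uz vx vy vz .   (corner + edge vectors)
// Rays: origin `from`, directions given by azimuth/elevation grids (radians).
// Returns hit coordinates and 1-based primitive index.
// [[Rcpp::export(name = ".raycast_cpp")]]
List raycast_cpp(NumericMatrix prim, NumericVector from, NumericVector az,
                 NumericVector el) {
  const int np = prim.nrow();
  std::vector<double> hx, hy, hz;
  std::vector<int> hid;
  const double ox = from[0], oy = from[1], oz = from[2];

  for (R_xlen_t ia = 0; ia < az.size(); ++ia) {
    const double ca = std::cos(az[ia]), sa = std::sin(az[ia]);
    for (R_xlen_t ie = 0; ie < el.size(); ++ie) {
      const double ce = std::cos(el[ie]), se = std::sin(el[ie]);
      const double dx = ce * ca, dy = ce * sa, dz = se;
      double best = R_PosInf;
      int best_id = -1;
      for (int p = 0; p < np; ++p) {
        const int type = (int)prim(p, 0);
        double t = R_PosInf;
        if (type == 0) {
          const double mx = ox - prim(p, 1), my = oy - prim(p, 2),
                       mz = oz - prim(p, 3);
          const double r = prim(p, 4);
          const double b = mx * dx + my * dy + mz * dz;
          const double c = mx * mx + my * my + mz * mz - r * r;
          const double disc = b * b - c;
          if (disc >= 0) {
            const double t0 = -b - std::sqrt(disc);
            if (t0 > 1e-9) t = t0;
          }
        } else if (type == 1) {
          const double ax = prim(p, 1), ay = prim(p, 2), az0 = prim(p, 3);
          double wx = prim(p, 4) - ax, wy = prim(p, 5) - ay,
                 wz = prim(p, 6) - az0;
          const double len = std::sqrt(wx * wx + wy * wy + wz * wz);
          if (len < 1e-12) continue;
          wx /= len; wy /= len; wz /= len;
          const double r = prim(p, 7);
          const double mx = ox - ax, my = oy - ay, mz = oz - az0;
          const double dw = dx * wx + dy * wy + dz * wz;
          const double mw = mx * wx + my * wy + mz * wz;
          const double A = 1.0 - dw * dw;
          const double B = (mx * dx + my * dy + mz * dz) - mw * dw;
          const double C = (mx * mx + my * my + mz * mz) - mw * mw - r * r;
          if (A > 1e-14) {
            const double disc = B * B - A * C;
            if (disc >= 0) {
              const double t0 = (-B - std::sqrt(disc)) / A;
              if (t0 > 1e-9) {
                const double s = mw + t0 * dw;  // axial coordinate of the hit
                if (s >= 0 && s <= len) t = t0;
              }
            }
          }
        } else if (type == 2) {
          const double px = prim(p, 1), py = prim(p, 2), pz = prim(p, 3);
          const double ux = prim(p, 4), uy = prim(p, 5), uz = prim(p, 6);
          const double vx = prim(p, 7), vy = prim(p, 8), vz = prim(p, 9);
          const double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
                       nz = ux * vy - uy * vx;
          const double denom = dx * nx + dy * ny + dz * nz;
          if (std::fabs(denom) > 1e-14) {
            const double t0 =
                ((px - ox) * nx + (py - oy) * ny + (pz - oz) * nz) / denom;
            if (t0 > 1e-9) {
              const double qx = ox + t0 * dx - px, qy = oy + t0 * dy - py,
                           qz = oz + t0 * dz - pz;
              const double uu = ux * ux + uy * uy + uz * uz;
              const double vv = vx * vx + vy * vy + vz * vz;
              const double qu = (qx * ux + qy * uy + qz * uz) / uu;
              const double qv = (qx * vx + qy * vy + qz * vz) / vv;
              if (qu >= 0 && qu <= 1 && qv >= 0 && qv <= 1) t = t0;
            }
          }
        }
        if (t < best) { best = t; best_id = p; }
      }
      if (best_id >= 0) {
        hx.push_back(ox + best * dx);
        hy.push_back(oy + best * dy);
        hz.push_back(oz + best * dz);
        hid.push_back(best_id + 1);
      }
    }
  }
  return List::create(_["x"] = wrap(hx), _["y"] = wrap(hy), _["z"] = wrap(hz),
                      _["prim"] = wrap(hid));
}

// nearest observed point (2D) for each query, via the same grid hash
// [[Rcpp::export(name = ".nn1_2d_cpp")]]
IntegerVector nn1_2d_cpp(NumericVector qx, NumericVector qy,
                         NumericVector rx, NumericVector ry) {
  const int nr = rx.size(), nq = qx.size();
  if (nr == 0) stop("no reference points");
  double lo0 = R_PosInf, lo1 = R_PosInf, hi0 = R_NegInf, hi1 = R_NegInf;
  for (int i = 0; i < nr; ++i) {
    lo0 = std::min(lo0, rx[i]); hi0 = std::max(hi0, rx[i]);
    lo1 = std::min(lo1, ry[i]); hi1 = std::max(hi1, ry[i]);
  }
  const double span = std::max({hi0 - lo0, hi1 - lo1, 1e-9});
  const double h = span / std::max(1.0, std::sqrt((double)nr / 2.0));
  std::unordered_map<uint64_t, std::vector<int>> cells;
  cells.reserve(nr * 2);
  for (int i = 0; i < nr; ++i) {
    const int64_t ci = (int64_t)std::floor(rx[i] / h);
    const int64_t cj = (int64_t)std::floor(ry[i] / h);
    cells[cell_key(ci, cj, 0)].push_back(i);
  }
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const int64_t ci = (int64_t)std::floor(qx[q] / h);
    const int64_t cj = (int64_t)std::floor(qy[q] / h);
    int best = -1;
    double bd = R_PosInf;
    for (int ring = 1; ; ++ring) {
      for (int64_t a = ci - ring; a <= ci + ring; ++a)
        for (int64_t b = cj - ring; b <= cj + ring; ++b) {
          auto it = cells.find(cell_key(a, b, 0));
          if (it == cells.end()) continue;
          for (int i : it->second) {
            const double dx = rx[i] - qx[q], dy = ry[i] - qy[q];
            const double d2 = dx * dx + dy * dy;
            if (d2 < bd) { bd = d2; best = i; }
          }
        }
      if (best >= 0 && std::sqrt(bd) <= ring * h) break;
      if (ring * h > 4.0 * span && best >= 0) break;
    }
    out[q] = best + 1;
  }
  return out;
}
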