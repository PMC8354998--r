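#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; Voronoi-region classification.
static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double sqdist(const double *p, const double *q) {
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

struct TriSoup {
  const NumericMatrix &V;
  const IntegerMatrix &F; // 1-based indices
  int ntri;
  TriSoup(const NumericMatrix &V_, const IntegerMatrix &F_)
      : V(V_), F(F_), ntri(F_.nrow()) {}
  void tri(int t, double *a, double *b, double *c) const {
    int i = F(t, 0) - 1, j = F(t, 1) - 1, k = F(t, 2) - 1;
    a[0] = V(i, 0); a[1] = V(i, 1); a[2] = V(i, 2);
    b[0] = V(j, 0); b[1] = V(j, 1); b[2] = V(j, 2);
    c[0] = V(k, 0); c[1] = V(k, 1); c[2] = V(k, 2);
  }
};

// Uniform grid over triangle AABBs.
struct TriGrid {
  double lo[3], h[3];
  int dim[3];
  std::vector<std::vector<int> > cells;

  int cell_index(int ix, int iy, int iz) const {
    return ix + dim[0] * (iy + dim[1] * iz);
  }
  int clampi(int v, int maxv) const {
    return v < 0 ? 0 : (v >= maxv ? maxv - 1 : v);
  }

  void build(const TriSoup &soup) {
    const NumericMatrix &V = soup.V;
    double hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::numeric_limits<double>::infinity();
      hi[d] = -std::numeric_limits<double>::infinity();
    }
    for (int i = 0; i < V.nrow(); ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], V(i, d));
        hi[d] = std::max(hi[d], V(i, d));
      }
    // target roughly 2 triangles per occupied cell, capped grid size
    double ext[3];
    double maxext = 0.0;
    for (int d = 0; d < 3; ++d) {
      ext[d] = std::max(hi[d] - lo[d], 1e-9);
      maxext = std::max(maxext, ext[d]);
    }
    double target = std::cbrt(std::max(1.0, (double)soup.ntri / 2.0));
    double cell = maxext / std::max(1.0, target);
    for (int d = 0; d < 3; ++d) {
      dim[d] = std::max(1, std::min(128, (int)std::ceil(ext[d] / cell)));
      h[d] = ext[d] / dim[d];
      if (h[d] <= 0) h[d] = 1e-9;
    }
    cells.assign((size_t)dim[0] * dim[1] * dim[2], std::vector<int>());
    double a[3], b[3], c[3];
    for (int t = 0; t < soup.ntri; ++t) {
      soup.tri(t, a, b, c);
      int cmin[3], cmax[3];
      for (int d = 0; d < 3; ++d) {
        double mn = std::min(a[d], std::min(b[d], c[d]));
        double mx = std::max(a[d], std::max(b[d], c[d]));
        cmin[d] = clampi((int)std::floor((mn - lo[d]) / h[d]), dim[d]);
        cmax[d] = clampi((int)std::floor((mx - lo[d]) / h[d]), dim[d]);
      }
      for (int iz = cmin[2]; iz <= cmax[2]; ++iz)
        for (int iy = cmin[1]; iy <= cmax[1]; ++iy)
          for (int ix = cmin[0]; ix <= cmax[0]; ++ix)
            cells[cell_index(ix, iy, iz)].push_back(t);
    }
  }

  // Expanding-shell query: examine shells of Chebyshev radius r until the
  // best squared distance found cannot be beaten by any unexamined cell.
  void query(const TriSoup &soup, const double *p, double &best_d2,
             int &best_t, double *best_q) const {
    int c0[3];
    for (int d = 0; d < 3; ++d)
      c0[d] = clampi((int)std::floor((p[d] - lo[d]) / h[d]), dim[d]);
    double hmin = std::min(h[0], std::min(h[1], h[2]));
    int rmax = std::max(dim[0], std::max(dim[1], dim[2]));
    best_d2 = std::numeric_limits<double>::infinity();
    best_t = -1;
    double a[3], b[3], c[3], q[3];
    for (int r = 0; r <= rmax; ++r) {
      if (best_t >= 0) {
        double bound = (double)(r - 1) * hmin;
        if (bound > 0 && bound * bound > best_d2) break;
      }
      for (int iz = c0[2] - r; iz <= c0[2] + r; ++iz) {
        if (iz < 0 || iz >= dim[2]) continue;
        for (int iy = c0[1] - r; iy <= c0[1] + r; ++iy) {
          if (iy < 0 || iy >= dim[1]) continue;
          for (int ix = c0[0] - r; ix <= c0[0] + r; ++ix) {
            if (ix < 0 || ix >= dim[0]) continue;
            int cr = std::max(std::abs(ix - c0[0]),
                              std::max(std::abs(iy - c0[1]),
                                       std::abs(iz - c0[2])));
            if (cr != r) continue; // shell boundary only
            const std::vector<int> &ts = cells[cell_index(ix, iy, iz)];
            for (size_t u = 0; u < ts.size(); ++u) {
              soup.tri(ts[u], a, b, c);
              closest_pt_triangle(p, a, b, c, q);
              double d2 = sqdist(p, q);
              if (d2 < best_d2 ||
                  (d2 == best_d2 && best_t >= 0 && ts[u] < best_t)) {
                best_d2 = d2;
                best_t = ts[u];
                best_q[0] = q[0]; best_q[1] = q[1]; best_q[2] = q[2];
              }
            }
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix points, NumericMatrix V,
                         IntegerMatrix F, bool accelerated) {
  TriSoup soup(V, F);
  int n = points.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);
  if (soup.ntri == 0) stop("reference mesh has no faces");

  if (accelerated) {
    TriGrid grid;
    grid.build(soup);
    double p[3], q[3];
    for (int i = 0; i < n; ++i) {
      p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
      double d2;
      int t;
      grid.query(soup, p, d2, t, q);
      dist[i] = std::sqrt(d2);
      closest(i, 0) = q[0]; closest(i, 1) = q[1]; closest(i, 2) = q[2];
      face[i] = t + 1;
    }
  } else {
    double p[3], a[3], b[3], c[3], q[3];
    for (int i = 0; i < n; ++i) {
      p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
      double best = std::numeric_limits<double>::infinity();
      int bt = -1;
      double bq[3] = {0, 0, 0};
      for (int t = 0; t < soup.ntri; ++t) {
        soup.tri(t, a, b, c);
        closest_pt_triangle(p, a, b, c, q);
        double d2 = sqdist(p, q);
        if (d2 < best) {
          best = d2;
          bt = t;
          bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
        }
      }
      dist[i] = std::sqrt(best);
      closest(i, 0) = bq[0]; closest(i, 1) = bq[1]; closest(i, 2) = bq[2];
      face[i] = bt + 1;
    }
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}
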