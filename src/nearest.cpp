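#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Closest point on a (closed) triangle abc to point p.
// Region classification after Ericson, Real-Time Collision Detection, ch. 5.
static inline void closest_pt_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3],
                                  double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

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
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

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

static inline double dist2(const double x[3], const double y[3]) {
  double d0 = x[0] - y[0], d1 = x[1] - y[1], d2 = x[2] - y[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

// [[Rcpp::export]]
double cpp_point_triangle_distance(NumericVector p, NumericMatrix tri) {
  double pp[3] = {p[0], p[1], p[2]};
  double a[3] = {tri(0, 0), tri(0, 1), tri(0, 2)};
  double b[3] = {tri(1, 0), tri(1, 1), tri(1, 2)};
  double c[3] = {tri(2, 0), tri(2, 1), tri(2, 2)};
  double q[3];
  closest_pt_tri(pp, a, b, c, q);
  return std::sqrt(dist2(pp, q));
}

// Independent oracle: minimise distance over an n x n barycentric grid
// (u = i/n, v = j/n with u + v <= 1). Deliberately brute-force.
// [[Rcpp::export]]
double cpp_point_triangle_grid_oracle(NumericVector p, NumericMatrix tri, int n) {
  double pp[3] = {p[0], p[1], p[2]};
  double a[3] = {tri(0, 0), tri(0, 1), tri(0, 2)};
  double ab[3] = {tri(1, 0) - a[0], tri(1, 1) - a[1], tri(1, 2) - a[2]};
  double ac[3] = {tri(2, 0) - a[0], tri(2, 1) - a[1], tri(2, 2) - a[2]};
  double best = R_PosInf;
  for (int i = 0; i <= n; ++i) {
    double u = (double)i / n;
    for (int j = 0; j <= n - i; ++j) {
      double v = (double)j / n;
      double q[3] = {a[0] + u * ab[0] + v * ac[0],
                     a[1] + u * ab[1] + v * ac[1],
                     a[2] + u * ab[2] + v * ac[2]};
      double d2 = dist2(pp, q);
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

struct TriGrid {
  int nx, ny, nz;
  double ox, oy, oz, hx, hy, hz;
  std::vector<std::vector<int> > cells;
  int cell_of(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
};

static void build_grid(const NumericMatrix &V, const IntegerMatrix &F, TriGrid &g) {
  int nf = F.nrow();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      if (V(i, k) < lo[k]) lo[k] = V(i, k);
      if (V(i, k) > hi[k]) hi[k] = V(i, k);
    }
  // a few cells per triangle, capped per axis
  int n = (int)std::ceil(2.0 * std::cbrt((double)std::max(nf, 1)));
  n = std::min(std::max(n, 1), 96);
  double ext[3];
  for (int k = 0; k < 3; ++k) {
    ext[k] = hi[k] - lo[k];
    if (ext[k] <= 0) ext[k] = 1e-9;
  }
  g.nx = n; g.ny = n; g.nz = n;
  g.ox = lo[0]; g.oy = lo[1]; g.oz = lo[2];
  g.hx = ext[0] / n * (1 + 1e-12) + 1e-300;
  g.hy = ext[1] / n * (1 + 1e-12) + 1e-300;
  g.hz = ext[2] / n * (1 + 1e-12) + 1e-300;
  g.cells.assign((size_t)n * n * n, std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int v = 0; v < 3; ++v) {
      int vi = F(f, v) - 1;
      for (int k = 0; k < 3; ++k) {
        double x = V(vi, k);
        if (x < tlo[k]) tlo[k] = x;
        if (x > thi[k]) thi[k] = x;
      }
    }
    int i0 = std::min(std::max((int)((tlo[0] - g.ox) / g.hx), 0), g.nx - 1);
    int i1 = std::min(std::max((int)((thi[0] - g.ox) / g.hx), 0), g.nx - 1);
    int j0 = std::min(std::max((int)((tlo[1] - g.oy) / g.hy), 0), g.ny - 1);
    int j1 = std::min(std::max((int)((thi[1] - g.oy) / g.hy), 0), g.ny - 1);
    int k0 = std::min(std::max((int)((tlo[2] - g.oz) / g.hz), 0), g.nz - 1);
    int k1 = std::min(std::max((int)((thi[2] - g.oz) / g.hz), 0), g.nz - 1);
    for (int iz = k0; iz <= k1; ++iz)
      for (int iy = j0; iy <= j1; ++iy)
        for (int ix = i0; ix <= i1; ++ix)
          g.cells[g.cell_of(ix, iy, iz)].push_back(f);
  }
}

// Nearest point on the triangle mesh (V, F) for each row of P.
// Returns distances, 1-based triangle indices and the foot points.
// Nearest-triangle ties resolved toward the lowest triangle index.
// [[Rcpp::export]]
List cpp_nearest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow(), nv = V.nrow();
  if (nf == 0) stop("reference mesh has no faces");
  TriGrid g;
  build_grid(V, F, g);
  // flat copies: the inner loop avoids Rcpp accessor overhead
  std::vector<double> Vf((size_t)nv * 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) Vf[(size_t)i * 3 + k] = V(i, k);
  std::vector<int> Ff((size_t)nf * 3);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) Ff[(size_t)f * 3 + k] = F(f, k) - 1;
  NumericVector dist(np);
  IntegerVector tri(np);
  NumericMatrix foot(np, 3);
  std::vector<int> stamp((size_t)nf, -1);
  double hmin = std::min(g.hx, std::min(g.hy, g.hz));
  int maxring = g.nx + g.ny + g.nz;

  for (int q = 0; q < np; ++q) {
    double p[3] = {P(q, 0), P(q, 1), P(q, 2)};
    int cx = std::min(std::max((int)((p[0] - g.ox) / g.hx), 0), g.nx - 1);
    int cy = std::min(std::max((int)((p[1] - g.oy) / g.hy), 0), g.ny - 1);
    int cz = std::min(std::max((int)((p[2] - g.oz) / g.hz), 0), g.nz - 1);
    double best = R_PosInf;
    int best_tri = -1;
    double best_pt[3] = {0, 0, 0};
    for (int r = 0; r <= maxring; ++r) {
      if (best_tri >= 0 && r >= 2) {
        double reach = (double)(r - 1) * hmin;
        if (reach * reach > best) break;
      }
      bool any_cell = false;
      int x0 = cx - r, x1 = cx + r, y0 = cy - r, y1 = cy + r, z0 = cz - r, z1 = cz + r;
      for (int iz = z0; iz <= z1; ++iz) {
        if (iz < 0 || iz >= g.nz) continue;
        for (int iy = y0; iy <= y1; ++iy) {
          if (iy < 0 || iy >= g.ny) continue;
          for (int ix = x0; ix <= x1; ++ix) {
            if (ix < 0 || ix >= g.nx) continue;
            // only the shell of the ring
            if (r > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1 &&
                iz != z0 && iz != z1) continue;
            any_cell = true;
            const std::vector<int> &cell = g.cells[g.cell_of(ix, iy, iz)];
            for (size_t t = 0; t < cell.size(); ++t) {
              int f = cell[t];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              const int *fv = &Ff[(size_t)f * 3];
              const double *a = &Vf[(size_t)fv[0] * 3];
              const double *b = &Vf[(size_t)fv[1] * 3];
              const double *c = &Vf[(size_t)fv[2] * 3];
              double pt[3];
              closest_pt_tri(p, a, b, c, pt);
              double d2 = dist2(p, pt);
              if (d2 < best || (d2 == best && f < best_tri)) {
                best = d2;
                best_tri = f;
                best_pt[0] = pt[0]; best_pt[1] = pt[1]; best_pt[2] = pt[2];
              }
            }
          }
        }
      }
      if (!any_cell && best_tri >= 0) break;
    }
    dist[q] = std::sqrt(best);
    tri[q] = best_tri + 1;
    foot(q, 0) = best_pt[0]; foot(q, 1) = best_pt[1]; foot(q, 2) = best_pt[2];
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri, _["point"] = foot);
}
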