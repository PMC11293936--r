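#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Trilinear interpolation of a 3D scalar grid at continuous voxel indices.
// vol is in R array order (column-major, dim = c(nx, ny, nz)); idx is an
// N x 3 matrix of 0-based indices with voxel centers at integer positions.
// Points outside the grid (beyond the outermost voxel centers) get `fill`.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix idx, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (nx == 1) fx = 0.0;
    if (ny == 1) fy = 0.0;
    if (nz == 1) fz = 0.0;
    const int x1 = (nx == 1) ? x0 : x0 + 1;
    const int y1 = (ny == 1) ? y0 : y0 + 1;
    const int z1 = (nz == 1) ? z0 : z0 + 1;
#define V(i, j, k) v[(R_xlen_t)(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Connected-component labeling of a 3D logical array (6-connectivity;
// use dim = c(nx, ny, 1) for 2D / 4-connectivity). Returns integer labels,
// 0 for background, components numbered from 1 in decreasing size order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  int next = 0;
  std::vector<R_xlen_t> sizes;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (m[s] != 1 || L[s] != 0) continue;
    ++next;
    R_xlen_t sz = 0;
    L[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front();
      q.pop();
      ++sz;
      int z = (int)(c / ((R_xlen_t)nx * ny));
      int r = (int)(c % ((R_xlen_t)nx * ny));
      int y = r / nx, x = r % nx;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t cc = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (m[cc] == 1 && L[cc] == 0) {
          L[cc] = next;
          q.push(cc);
        }
      }
    }
    sizes.push_back(sz);
  }
  // relabel in decreasing size order
  std::vector<int> order(next), rank(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return sizes[a] > sizes[b]; });
  for (int i = 0; i < next; ++i) rank[order[i]] = i + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (L[s] > 0) L[s] = rank[L[s] - 1];
  lab.attr("dim") = dim;
  return lab;
}

// City-block distance (in voxels) from each foreground voxel to the nearest
// background voxel, by multi-source BFS. Background voxels get 0; the array
// border counts as background. Used for cortical-shell peeling.
// [[Rcpp::export]]
IntegerVector border_distance_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector dist(n);
  const int *m = LOGICAL(mask);
  int *D = INTEGER(dist);
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (m[s] != 1) {
      D[s] = 0;
      q.push(s);
    } else {
      int z = (int)(s / ((R_xlen_t)nx * ny));
      int r = (int)(s % ((R_xlen_t)nx * ny));
      int y = r / nx, x = r % nx;
      bool border = (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 ||
                     z == 0 || z == nz - 1);
      if (border) {
        D[s] = 1;  // touching the array edge: treat just outside as background
        q.push(s);
      } else {
        D[s] = -1;
      }
    }
  }
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    R_xlen_t c = q.front();
    q.pop();
    int z = (int)(c / ((R_xlen_t)nx * ny));
    int r = (int)(c % ((R_xlen_t)nx * ny));
    int y = r / nx, x = r % nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t cc = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (D[cc] == -1) {
        D[cc] = D[c] + 1;
        q.push(cc);
      }
    }
  }
  dist.attr("dim") = dim;
  return dist;
}

// Separable box smoothing (radius k voxels per axis) of a 3D array.
// [[Rcpp::export]]
NumericVector box_smooth_cpp(NumericVector vol, IntegerVector dim, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector a(clone(vol)), b(n);
  auto pass = [&](NumericVector &src, NumericVector &dst, int len,
                  R_xlen_t stride, R_xlen_t nlines,
                  std::function<R_xlen_t(R_xlen_t)> base) {
    for (R_xlen_t l = 0; l < nlines; ++l) {
      R_xlen_t o = base(l);
      double run = 0.0;
      int cnt = 0;
      for (int i = 0; i < std::min(k + 1, len); ++i) {
        run += src[o + (R_xlen_t)i * stride];
        ++cnt;
      }
      for (int i = 0; i < len; ++i) {
        dst[o + (R_xlen_t)i * stride] = run / cnt;
        int add = i + k + 1, drop = i - k;
        if (add < len) { run += src[o + (R_xlen_t)add * stride]; ++cnt; }
        if (drop >= 0) { run -= src[o + (R_xlen_t)drop * stride]; --cnt; }
      }
    }
  };
  // x
  pass(a, b, nx, 1, (R_xlen_t)ny * nz,
       [&](R_xlen_t l) { return l * nx; });
  // y
  pass(b, a, ny, nx, (R_xlen_t)nx * nz, [&](R_xlen_t l) {
    R_xlen_t z = l / nx, x = l % nx;
    return x + z * (R_xlen_t)nx * ny;
  });
  // z
  pass(a, b, nz, (R_xlen_t)nx * ny, (R_xlen_t)nx * ny,
       [&](R_xlen_t l) { return l; });
  return b;
}
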