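// Compiled kernels for image-derived structural descriptors:
// component labelling, Euclidean distance transform, local thickness
// (largest inscribed sphere), topology-preserving thinning, and the
// exact permutation null for small-sample Spearman tests.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// face-connected component labelling of the pore phase (pore = !solid).
// Labels are deterministic: ordered by component size (descending), ties
// broken by the smallest linear index of a member voxel.

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector solid, IntegerVector dims) {
  const int dim = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (dim == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> sizes, seeds;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (solid[start] || lab[start]) continue;
    ++next;
    sizes.push_back(0); seeds.push_back(start);
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++sizes[next - 1];
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      int nn = (dim == 3) ? 6 : 4;
      for (int k = 0; k < nn; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (!solid[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  // deterministic relabelling
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (sizes[a] != sizes[b]) return sizes[a] > sizes[b];
    return seeds[a] < seeds[b];
  });
  std::vector<int> newlab(next + 1, 0);
  for (int i = 0; i < next; ++i) newlab[order[i] + 1] = i + 1;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = newlab[lab[i]];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance from each pore voxel centre to the nearest solid voxel centre.

static void dt1d(const double* f, double* d, int n, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector solid, IntegerVector dims) {
  const int dim = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (dim == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  const double BIG = 1e18;
  for (R_xlen_t i = 0; i < n; ++i) d[i] = solid[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f.data(), dd.data(), nx, v, z);
      for (int x = 0; x < nx; ++x) d[base + x] = dd[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)nx * y];
      dt1d(f.data(), dd.data(), ny, v, z);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nx * y] = dd[y];
    }
  // z pass
  if (dim == 3)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        R_xlen_t stride = (R_xlen_t)nx * ny;
        for (int zz = 0; zz < nz; ++zz) f[zz] = d[base + stride * zz];
        dt1d(f.data(), dd.data(), nz, v, z);
        for (int zz = 0; zz < nz; ++zz) d[base + stride * zz] = dd[zz];
      }
  d.attr("dim") = dims;
  return d;
}

// ---------------------------------------------------------------------------
// local thickness (Hildebrand-Ruegsegger): per pore voxel, the diameter of
// the largest sphere fully contained in the pore space that covers it.
// Sphere radius at candidate centre c is r(c) = dist(c, nearest solid) - 1/2
// (the phase interface sits half-way between voxel centres); voxel v is
// covered when |v - c| <= r(c).  Returned in voxel units (diameter).

// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector solid, IntegerVector dims) {
  const int dim = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (dim == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d2 = cpp_edt_sq(solid, dims);
  NumericVector th(n);
  bool any_solid = false;
  for (R_xlen_t i = 0; i < n; ++i) if (solid[i]) { any_solid = true; break; }
  if (!any_solid) {
    // no solid anywhere: thickness is unbounded; report the domain extent
    double ext = std::max(nx, std::max(ny, nz));
    for (R_xlen_t i = 0; i < n; ++i) th[i] = ext;
    th.attr("dim") = dims;
    return th;
  }
  std::vector<R_xlen_t> pores;
  pores.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) if (!solid[i]) pores.push_back(i);
  std::sort(pores.begin(), pores.end(), [&](R_xlen_t a, R_xlen_t b) {
    return d2[a] > d2[b];
  });
  for (R_xlen_t pi = 0; pi < (R_xlen_t)pores.size(); ++pi) {
    R_xlen_t c = pores[pi];
    double r = std::sqrt(d2[c]) - 0.5;
    if (r < 0) r = 0;
    double diam = 2.0 * r;
    int cx = c % nx, cy = (c / nx) % ny, cz = c / ((R_xlen_t)nx * ny);
    int ir = (int)std::floor(r);
    double r2 = r * r;
    int z0 = (dim == 3) ? std::max(0, cz - ir) : 0;
    int z1 = (dim == 3) ? std::min(nz - 1, cz + ir) : 0;
    for (int z = z0; z <= z1; ++z) {
      double dz2 = (double)(z - cz) * (z - cz);
      for (int y = std::max(0, cy - ir); y <= std::min(ny - 1, cy + ir); ++y) {
        double dy2 = (double)(y - cy) * (y - cy);
        if (dz2 + dy2 > r2) continue;
        for (int x = std::max(0, cx - ir); x <= std::min(nx - 1, cx + ir); ++x) {
          double dd = dz2 + dy2 + (double)(x - cx) * (x - cx);
          if (dd > r2) continue;
          R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (!solid[v] && th[v] < diam) th[v] = diam;
        }
      }
    }
  }
  th.attr("dim") = dims;
  return th;
}

// ---------------------------------------------------------------------------
// topology-preserving thinning of the pore phase to a curve skeleton.
// A border voxel is removed when it is a simple point (object connectivity
// 8/26, background connectivity 4/6) and not a curve endpoint.  Sequential
// directional sub-iterations keep the result deterministic and centred.

struct Nbhd {
  int dim, nx, ny, nz;
};

static inline bool inb(int x, int lo, int hi) { return x >= lo && x <= hi; }

// count object components in the 26(8)-neighbourhood, and background
// components 6(4)-connected within the 18(4)-neighbourhood touching centre
static bool is_simple(const std::vector<uint8_t>& img, int x, int y, int z,
                      int nx, int ny, int nz, int dim) {
  // local 3x3(x3) copy, centre removed
  uint8_t loc[27];
  int cnt = 0;
  int nzl = (dim == 3) ? 3 : 1;
  for (int dz = 0; dz < nzl; ++dz)
    for (int dy = 0; dy < 3; ++dy)
      for (int dx = 0; dx < 3; ++dx) {
        int xx = x + dx - 1, yy = y + dy - 1, zz = (dim == 3) ? z + dz - 1 : 0;
        uint8_t v = 0;
        if (inb(xx, 0, nx - 1) && inb(yy, 0, ny - 1) && inb(zz, 0, nz - 1))
          v = img[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        loc[dx + 3 * (dy + 3 * dz)] = v;
        if (v && !(dx == 1 && dy == 1 && dz == (dim == 3 ? 1 : 0))) ++cnt;
      }
  int centre = 1 + 3 * (1 + 3 * (dim == 3 ? 1 : 0));
  loc[centre] = 0;
  if (cnt == 0) return false;
  // object components, full connectivity, excluding centre
  {
    int seen[27] = {0};
    int comps = 0;
    int nmax = (dim == 3) ? 27 : 9;
    for (int i = 0; i < nmax; ++i) {
      if (!loc[i] || seen[i]) continue;
      ++comps;
      if (comps > 1) return false;
      std::vector<int> st{i};
      seen[i] = 1;
      while (!st.empty()) {
        int v = st.back(); st.pop_back();
        int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = vx + dx, yy = vy + dy, zz = vz + dz;
              if (!inb(xx, 0, 2) || !inb(yy, 0, 2)) continue;
              if (dim == 3) { if (!inb(zz, 0, 2)) continue; }
              else if (zz != 0) continue;
              int w = xx + 3 * (yy + 3 * zz);
              if (loc[w] && !seen[w]) { seen[w] = 1; st.push_back(w); }
            }
      }
    }
    if (comps != 1) return false;
  }
  // background components, face connectivity, restricted to the
  // 18(8)-neighbourhood, that are face-adjacent to the centre
  {
    int seen[27] = {0};
    int comps = 0;
    const int fdx[6] = {-1, 1, 0, 0, 0, 0};
    const int fdy[6] = {0, 0, -1, 1, 0, 0};
    const int fdz[6] = {0, 0, 0, 0, -1, 1};
    int nfc = (dim == 3) ? 6 : 4;
    for (int k = 0; k < nfc; ++k) {
      int sx = 1 + fdx[k], sy = 1 + fdy[k], sz = (dim == 3 ? 1 : 0) + fdz[k];
      int s = sx + 3 * (sy + 3 * sz);
      if (loc[s] || seen[s]) continue;
      ++comps;
      if (comps > 1) return false;
      std::vector<int> st{s};
      seen[s] = 1;
      while (!st.empty()) {
        int v = st.back(); st.pop_back();
        int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
        for (int k2 = 0; k2 < nfc; ++k2) {
          int xx = vx + fdx[k2], yy = vy + fdy[k2], zz = vz + fdz[k2];
          if (!inb(xx, 0, 2) || !inb(yy, 0, 2)) continue;
          if (dim == 3) { if (!inb(zz, 0, 2)) continue; }
          else if (zz != 0) continue;
          // restrict to 18-neighbourhood in 3D (exclude corners)
          if (dim == 3) {
            int manh = std::abs(xx - 1) + std::abs(yy - 1) + std::abs(zz - 1);
            if (manh > 2) continue;
          }
          int w = xx + 3 * (yy + 3 * zz);
          if (!loc[w] && !seen[w]) { seen[w] = 1; st.push_back(w); }
        }
      }
    }
    if (comps != 1) return false;
  }
  return true;
}

static int nbr_count_full(const std::vector<uint8_t>& img, int x, int y, int z,
                          int nx, int ny, int nz, int dim) {
  int cnt = 0;
  int zlo = (dim == 3) ? -1 : 0, zhi = (dim == 3) ? 1 : 0;
  for (int dz = zlo; dz <= zhi; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (!inb(xx, 0, nx - 1) || !inb(yy, 0, ny - 1) || !inb(zz, 0, nz - 1)) continue;
        if (img[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) ++cnt;
      }
  return cnt;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector solid, IntegerVector dims) {
  const int dim = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (dim == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = solid[i] ? 0 : 1;
  const int fdx[6] = {0, 0, -1, 1, 0, 0};
  const int fdy[6] = {-1, 1, 0, 0, 0, 0};
  const int fdz[6] = {0, 0, 0, 0, -1, 1};
  int ndir = (dim == 3) ? 6 : 4;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < ndir; ++d) {
      std::vector<R_xlen_t> cand;
      for (R_xlen_t i = 0; i < n; ++i) {
        if (!img[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
        int xx = x + fdx[d], yy = y + fdy[d], zz = z + fdz[d];
        bool border = true;
        if (inb(xx, 0, nx - 1) && inb(yy, 0, ny - 1) && inb(zz, 0, nz - 1))
          border = !img[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        if (!border) continue;
        cand.push_back(i);
      }
      for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ++ci) {
        R_xlen_t i = cand[ci];
        if (!img[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
        if (nbr_count_full(img, x, y, z, nx, ny, nz, dim) <= 1) continue; // endpoint
        if (is_simple(img, x, y, z, nx, ny, nz, dim)) {
          img[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// two-sided exact permutation p-value for the Spearman coefficient
// (small n); rx, ry are rank vectors (may contain tie midranks).

// [[Rcpp::export]]
double cpp_spearman_perm_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> x(rx.begin(), rx.end()), y(ry.begin(), ry.end());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) {
    x[i] -= mx; sx += x[i] * x[i];
    y[i] -= my; sy += y[i] * y[i];
  }
  if (sx <= 0 || sy <= 0) return NA_REAL;
  double denom = std::sqrt(sx * sy);
  double obs = 0;
  for (int i = 0; i < n; ++i) obs += x[i] * y[i];
  double obs_r = std::fabs(obs / denom);
  // Heap's algorithm over permutations of y
  std::vector<int> cidx(n, 0);
  std::vector<double> yp(y);
  long long count = 0, total = 0;
  auto tally = [&]() {
    double s = 0;
    for (int i = 0; i < n; ++i) s += x[i] * yp[i];
    if (std::fabs(s / denom) >= obs_r - 1e-12) ++count;
    ++total;
  };
  tally();
  int i = 0;
  while (i < n) {
    if (cidx[i] < i) {
      int j = (i % 2 == 0) ? 0 : cidx[i];
      std::swap(yp[j], yp[i]);
      tally();
      ++cidx[i];
      i = 0;
    } else {
      cidx[i] = 0;
      ++i;
    }
  }
  return (double)count / (double)total;
}
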