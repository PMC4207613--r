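#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// 3D image primitives for stacks stored as R arrays with dim = c(nz, ny, nx)
// (column-major, so linear index = z + nz*(y + ny*x)).

static inline int reflect_idx(int i, int n) {
  // reflect-101 boundary: -1 -> 1, n -> n-2
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector arr, double sigma_z, double sigma_y,
                              double sigma_x) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = arr.size();
  std::vector<double> cur(arr.begin(), arr.end()), tmp(n);

  const double sig[3] = {sigma_z, sigma_y, sigma_x};
  const int len[3] = {nz, ny, nx};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};

  for (int ax = 0; ax < 3; ++ax) {
    if (sig[ax] <= 0) continue;
    std::vector<double> k = gauss_kernel(sig[ax]);
    int r = ((int)k.size() - 1) / 2;
    int nline = len[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int d1 = (ax == 0) ? 1 : 0;
    int d2 = (ax == 2) ? 1 : 2;
    int n1 = len[d1], n2 = len[d2];
    R_xlen_t st1 = stride[d1], st2 = stride[d2];
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t base = (R_xlen_t)i1 * st1 + (R_xlen_t)i2 * st2;
        for (int i = 0; i < nline; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int ii = reflect_idx(i + j, nline);
            acc += k[j + r] * cur[base + (R_xlen_t)ii * st];
          }
          tmp[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::swap(cur, tmp);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;

  // neighbor offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v / ((R_xlen_t)nz * ny));
      int rem = (int)(v % ((R_xlen_t)nz * ny));
      int y = rem / nz, z = rem % nz;
      for (auto &d : nb) {
        int zz = z + d[0], yy = y + d[1], xx = x + d[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix cpp_local_max3(NumericVector arr, double threshold) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> zs, ys, xs;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t v = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        double val = arr[v];
        if (!(val > threshold)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (dz == 0 && dy == 0 && dx == 0) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              if (arr[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] > val)
                ismax = false;
            }
        if (ismax) {
          zs.push_back(z + 1);
          ys.push_back(y + 1);
          xs.push_back(x + 1);
        }
      }
  IntegerMatrix out((int)zs.size(), 3);
  for (int i = 0; i < (int)zs.size(); ++i) {
    out(i, 0) = zs[i];
    out(i, 1) = ys[i];
    out(i, 2) = xs[i];
  }
  colnames(out) = CharacterVector::create("z", "y", "x");
  return out;
}
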