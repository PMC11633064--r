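// 3D image utilities: connected-component labeling, ball dilation, separable
// Gaussian filtering and grid resampling. All operate on plain 3D arrays
// (dim = c(X, Y, Z), column-major).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static void get_dims3(const SEXP x, int d[3]) {
  IntegerVector dm = Rf_getAttrib(x, R_DimSymbol);
  if (dm.size() != 3) stop("expected a 3-d array");
  for (int i = 0; i < 3; ++i) d[i] = dm[i];
}

// Offsets for 6/18/26 connectivity.
static std::vector<std::array<int, 3>> conn_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Label foreground (x != 0) components; returns integer array of labels
// 1..n_components, 0 for background.
// [[Rcpp::export]]
IntegerVector label3d_cpp(NumericVector x, int connectivity) {
  int d[3];
  get_dims3(x, d);
  const int X = d[0], Y = d[1], Z = d[2];
  const long n = (long)X * Y * Z;
  IntegerVector lab(n);
  lab.attr("dim") = IntegerVector::create(X, Y, Z);
  auto off = conn_offsets(connectivity);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (x[s] == 0 || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int i = v % X, j = (v / X) % Y, k = v / ((long)X * Y);
      for (auto &o : off) {
        const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || ii >= X || jj < 0 || jj >= Y || kk < 0 || kk >= Z)
          continue;
        const long w = ii + (long)X * (jj + (long)Y * kk);
        if (x[w] != 0 && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Binary dilation with a Euclidean ball of the given voxel radius
// (offsets with dx^2+dy^2+dz^2 <= r^2; r = 1 gives the 6-neighbourhood ball).
// [[Rcpp::export]]
NumericVector dilate_ball3d_cpp(NumericVector x, double radius) {
  int d[3];
  get_dims3(x, d);
  const int X = d[0], Y = d[1], Z = d[2];
  NumericVector y((long)X * Y * Z);
  y.attr("dim") = IntegerVector::create(X, Y, Z);
  const int r = (int)std::floor(radius + 1e-9);
  const double r2 = radius * radius + 1e-9;
  std::vector<std::array<int, 3>> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r2) off.push_back({dx, dy, dz});
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const long v = i + (long)X * (j + (long)Y * k);
        if (x[v] == 0) continue;
        for (auto &o : off) {
          const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= X || jj < 0 || jj >= Y || kk < 0 || kk >= Z)
            continue;
          y[ii + (long)X * (jj + (long)Y * kk)] = 1.0;
        }
      }
  return y;
}

// Separable Gaussian filter with truncation at 3 sigma; sigma in voxels.
// Border handling: renormalised truncated kernel (filter weights of
// out-of-range taps are dropped and the remainder rescaled to sum 1).
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector x, double sigma) {
  int d[3];
  get_dims3(x, d);
  const int X = d[0], Y = d[1], Z = d[2];
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  NumericVector a = clone(x), b((long)X * Y * Z);
  const int dims[3] = {X, Y, Z};
  const long strides[3] = {1, X, (long)X * Y};
  double *pa = a.begin(), *pb = b.begin();
  for (int ax = 0; ax < 3; ++ax) {
    const int L = dims[ax];
    const long s = strides[ax];
    for (int k = 0; k < Z; ++k)
      for (int j = 0; j < Y; ++j)
        for (int i = 0; i < X; ++i) {
          const int pos = ax == 0 ? i : (ax == 1 ? j : k);
          const long v = i + (long)X * (j + (long)Y * k);
          double acc = 0.0, wsum = 0.0;
          const int t0 = std::max(-r, -pos), t1 = std::min(r, L - 1 - pos);
          for (int t = t0; t <= t1; ++t) {
            acc += ker[t + r] * pa[v + t * s];
            wsum += ker[t + r];
          }
          pb[v] = acc / wsum;
        }
    std::swap(pa, pb);
  }
  if (pa != a.begin()) std::copy(pa, pa + a.size(), a.begin());
  b.attr("dim") = R_NilValue;
  a.attr("dim") = IntegerVector::create(X, Y, Z);
  return a;
}

// Resample a 3D grid to new dimensions. ratio[a] = out_spacing / in_spacing
// per axis; source coordinate of output voxel i is (i + 0.5) * ratio - 0.5,
// clamped to the grid. mode 0 = nearest neighbour, 1 = trilinear.
// [[Rcpp::export]]
NumericVector resample3d_cpp(NumericVector x, IntegerVector out_dim,
                             NumericVector ratio, int mode) {
  int d[3];
  get_dims3(x, d);
  const int X = d[0], Y = d[1], Z = d[2];
  const int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector y((long)Xo * Yo * Zo);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  auto src = [](int i, double r, int lim) {
    double c = (i + 0.5) * r - 0.5;
    if (c < 0) c = 0;
    if (c > lim - 1) c = lim - 1;
    return c;
  };
  for (int k = 0; k < Zo; ++k) {
    const double cz = src(k, ratio[2], Z);
    for (int j = 0; j < Yo; ++j) {
      const double cy = src(j, ratio[1], Y);
      for (int i = 0; i < Xo; ++i) {
        const double cx = src(i, ratio[0], X);
        const long o = i + (long)Xo * (j + (long)Yo * k);
        if (mode == 0) {
          const int ii = (int)std::lround(cx), jj = (int)std::lround(cy),
                    kk = (int)std::lround(cz);
          y[o] = x[ii + (long)X * (jj + (long)Y * kk)];
        } else {
          const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                    z0 = (int)std::floor(cz);
          const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
                    z1 = std::min(z0 + 1, Z - 1);
          const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                if (wgt == 0) continue;
                const int ii = dx ? x1 : x0, jj = dy ? y1 : y0,
                          kk = dz ? z1 : z0;
                acc += wgt * x[ii + (long)X * (jj + (long)Y * kk)];
              }
          y[o] = acc;
        }
      }
    }
  }
  return y;
}
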