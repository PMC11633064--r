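// Low-level kernels for the compact 3D CNN stack.
//
// Tensor layout: numeric array with dim = c(X, Y, Z, C, N) — spatial axes
// fastest, then channel, then batch, matching R's column-major order so that
// one channel of one batch item is a contiguous block. 3x3x3 convolutions
// are direct loops over contiguous row runs (cache-resident at the channel
// widths this stack uses). Batch norm + leaky ReLU are fused
// single-pass kernels; transposed 2x2x2 stride-2 convolutions and 2x2x2 max
// pooling are direct loops as well.

#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

static void get_dims5(const NumericVector &x, int d[5]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("expected a 5-d tensor (X, Y, Z, C, N)");
  for (int i = 0; i < 5; ++i) d[i] = dm[i];
}

// Direct 3x3x3 same-padding convolution. At the channel widths this stack
// uses, a direct loop with contiguous row runs is cache-resident and far
// cheaper than im2col + gemm. Arithmetic runs in single precision (the
// parameters and activations are stored as doubles at the R level); weight
// gradients are accumulated per row run into doubles.
// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  int d[5];
  get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Cout = w.nrow();
  if (w.ncol() != C * 27) stop("weight/input channel mismatch");
  const long vox = (long)X * Y * Z;
  NumericVector y(vox * Cout * N);
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout, N);
  static std::vector<float> xf, yf;
  xf.resize(x.size());
  for (long t = 0; t < (long)x.size(); ++t) xf[t] = (float)x[t];
  yf.resize(vox);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      float *yc = yf.data();
      const float bc = (float)b[co];
      for (long t = 0; t < vox; ++t) yc[t] = bc;
      for (int c = 0; c < C; ++c) {
        const float *xc = xf.data() + vox * (c + (long)C * n);
        for (int dc = -1; dc <= 1; ++dc)
          for (int db = -1; db <= 1; ++db)
            for (int da = -1; da <= 1; ++da) {
              const int off = (da + 1) + 3 * (db + 1) + 9 * (dc + 1);
              const float wv = (float)w(co, c * 27 + off);
              if (wv == 0.0f) continue;
              const int i0 = std::max(0, -da), i1 = std::min(X, X - da);
              for (int k = 0; k < Z; ++k) {
                const int sk = k + dc;
                if (sk < 0 || sk >= Z) continue;
                for (int j = 0; j < Y; ++j) {
                  const int sj = j + db;
                  if (sj < 0 || sj >= Y) continue;
                  float *__restrict__ dst = yc + i0 + (long)X * (j + (long)Y * k);
                  const float *__restrict__ src =
                      xc + (i0 + da) + (long)X * (sj + (long)Y * sk);
                  const int len = i1 - i0;
                  for (int i = 0; i < len; ++i) dst[i] += wv * src[i];
                }
              }
            }
      }
      double *yout = y.begin() + vox * (co + (long)Cout * n);
      for (long t = 0; t < vox; ++t) yout[t] = (double)yc[t];
    }
  return y;
}

// Backward of the direct convolution: input gradient, weight gradient and
// bias gradient fused into one loop nest over the same row runs.
// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericMatrix w, NumericVector gy,
               bool need_gx) {
  int d[5];
  get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Cout = w.nrow();
  const long vox = (long)X * Y * Z;
  NumericVector gx(need_gx ? x.size() : 1);
  if (need_gx) gx.attr("dim") = x.attr("dim");
  NumericMatrix gw(Cout, C * 27);
  NumericVector gb(Cout);
  static std::vector<float> xf, gf, gxf;
  xf.resize(x.size());
  gf.resize(gy.size());
  for (long t = 0; t < (long)x.size(); ++t) xf[t] = (float)x[t];
  for (long t = 0; t < (long)gy.size(); ++t) gf[t] = (float)gy[t];
  if (need_gx) {
    gxf.assign(x.size(), 0.0f);
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float *gc = gf.data() + vox * (co + (long)Cout * n);
      double gbacc = 0.0;
      for (long t = 0; t < vox; ++t) gbacc += gc[t];
      gb[co] += gbacc;
      for (int c = 0; c < C; ++c) {
        const float *xc = xf.data() + vox * (c + (long)C * n);
        float *gxc = need_gx ? gxf.data() + vox * (c + (long)C * n) : nullptr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int db = -1; db <= 1; ++db)
            for (int da = -1; da <= 1; ++da) {
              const int off = (da + 1) + 3 * (db + 1) + 9 * (dc + 1);
              const float wv = (float)w(co, c * 27 + off);
              double gwacc = 0.0;
              const int i0 = std::max(0, -da), i1 = std::min(X, X - da);
              for (int k = 0; k < Z; ++k) {
                const int sk = k + dc;
                if (sk < 0 || sk >= Z) continue;
                for (int j = 0; j < Y; ++j) {
                  const int sj = j + db;
                  if (sj < 0 || sj >= Y) continue;
                  const float *__restrict__ gr = gc + i0 + (long)X * (j + (long)Y * k);
                  const long soff = (i0 + da) + (long)X * (sj + (long)Y * sk);
                  const float *__restrict__ xr = xc + soff;
                  const int len = i1 - i0;
                  float racc = 0.0f;
                  if (need_gx) {
                    float *__restrict__ gdst = gxc + soff;
                    for (int i = 0; i < len; ++i) {
                      racc += gr[i] * xr[i];
                      gdst[i] += gr[i] * wv;
                    }
                  } else {
                    for (int i = 0; i < len; ++i) racc += gr[i] * xr[i];
                  }
                  gwacc += racc;
                }
              }
              gw(co, c * 27 + off) += gwacc;
            }
      }
    }
  if (need_gx) {
    for (long t = 0; t < (long)x.size(); ++t) gx[t] = (double)gxf[t];
  }
  SEXP gxOut = need_gx ? (SEXP)gx : R_NilValue;
  return List::create(_["gx"] = gxOut, _["gw"] = gw, _["gb"] = gb);
}

// Fused batch norm + leaky ReLU forward. In training mode the per-channel
// statistics come from the batch (biased variance) and updated running
// statistics are returned; in evaluation mode the running statistics are
// used. Returns y, xhat (cached for backward) and invstd.
// [[Rcpp::export]]
List bn_act_fw(NumericVector z, NumericVector g, NumericVector be,
               NumericVector rm, NumericVector rv, bool training,
               double momentum, double eps, double slope) {
  int d[5];
  get_dims5(z, d);
  const long vox = (long)d[0] * d[1] * d[2];
  const int C = d[3], N = d[4];
  const long M = vox * N;
  NumericVector mu(C), va(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double *zc = z.begin() + vox * (c + (long)C * n);
        for (long t = 0; t < vox; ++t) {
          s += zc[t];
          s2 += zc[t] * zc[t];
        }
      }
      mu[c] = s / M;
      va[c] = std::max(s2 / M - mu[c] * mu[c], 0.0);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rm[c];
      va[c] = rv[c];
    }
  }
  NumericVector y(z.size()), xhat(z.size()), invstd(C);
  y.attr("dim") = z.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(va[c] + eps);
    invstd[c] = is;
    const double gc = g[c], bc = be[c], mc = mu[c];
    for (int n = 0; n < N; ++n) {
      const long o = vox * (c + (long)C * n);
      const double *zc = z.begin() + o;
      double *yc = y.begin() + o, *xc = xhat.begin() + o;
      for (long t = 0; t < vox; ++t) {
        const double xh = (zc[t] - mc) * is;
        xc[t] = xh;
        const double y0 = gc * xh + bc;
        yc[t] = y0 > 0 ? y0 : slope * y0;
      }
    }
  }
  List out = List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
  if (training) {
    NumericVector rmn(C), rvn(C);
    for (int c = 0; c < C; ++c) {
      rmn[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rvn[c] = (1 - momentum) * rv[c] + momentum * va[c];
    }
    out["rm_new"] = rmn;
    out["rv_new"] = rvn;
  }
  return out;
}

// Fused backward of leaky ReLU + batch norm (training statistics).
// y is the block output (its sign recovers the activation mask).
// Returns gz (gradient w.r.t. the convolution output), gg, gbe.
// [[Rcpp::export]]
List bn_act_bw(NumericVector gy, NumericVector y, NumericVector xhat,
               NumericVector invstd, NumericVector g, double slope) {
  IntegerVector dm = gy.attr("dim");
  const long vox = (long)dm[0] * dm[1] * dm[2];
  const int C = dm[3], N = dm[4];
  const long M = vox * N;
  NumericVector gz(gy.size()), gg(C), gbe(C);
  gz.attr("dim") = gy.attr("dim");
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const long o = vox * (c + (long)C * n);
      const double *gc = gy.begin() + o, *yc = y.begin() + o,
                   *xc = xhat.begin() + o;
      double *zc = gz.begin() + o;
      for (long t = 0; t < vox; ++t) {
        const double gym = gc[t] * (yc[t] > 0 ? 1.0 : slope);
        zc[t] = gym;  // stash gym; rescaled below
        s1 += gym;
        s2 += gym * xc[t];
      }
    }
    gbe[c] = s1;
    gg[c] = s2;
    const double gcoef = g[c], is = invstd[c];
    const double m1 = gcoef * s1 / M, m2 = gcoef * s2 / M;
    for (int n = 0; n < N; ++n) {
      const long o = vox * (c + (long)C * n);
      const double *xc = xhat.begin() + o;
      double *zc = gz.begin() + o;
      for (long t = 0; t < vox; ++t) {
        zc[t] = is * (gcoef * zc[t] - m1 - xc[t] * m2);
      }
    }
  }
  return List::create(_["gz"] = gz, _["gg"] = gg, _["gbe"] = gbe);
}

// 2x2x2 max pooling, stride 2. Returns pooled tensor and 1-based argmax
// indices into the flat input, so the backward pass is a plain R scatter.
// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x) {
  int d[5];
  get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  if (X % 2 || Y % 2 || Z % 2) stop("spatial dims must be even for pooling");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const long vox = (long)X * Y * Z, voxo = (long)Xo * Yo * Zo;
  NumericVector y(voxo * C * N);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
  IntegerVector idx(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = px + vox * (c + (long)C * n);
      const long obase = voxo * (c + (long)C * n);
      for (int k = 0; k < Zo; ++k)
        for (int j = 0; j < Yo; ++j)
          for (int i = 0; i < Xo; ++i) {
            double best = -1e300;
            long bidx = 0;
            for (int dc = 0; dc < 2; ++dc)
              for (int db = 0; db < 2; ++db)
                for (int da = 0; da < 2; ++da) {
                  const long s = (2 * i + da) +
                                 (long)X * ((2 * j + db) +
                                            (long)Y * (2 * k + dc));
                  if (xc[s] > best) {
                    best = xc[s];
                    bidx = s;
                  }
                }
            const long o = obase + i + (long)Xo * (j + (long)Yo * k);
            py[o] = best;
            pi[o] = (int)(vox * (c + (long)C * n) + bidx + 1);
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Transposed convolution, kernel 2, stride 2 (doubles each spatial dim).
// w: (Cout, Cin*8), kernel offset order ci*8 + (da + 2*db + 4*dc).
// [[Rcpp::export]]
NumericVector upconv3d_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  int d[5];
  get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Cout = w.nrow();
  if (w.ncol() != C * 8) stop("weight/input channel mismatch");
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const long vox = (long)X * Y * Z, voxo = (long)Xo * Yo * Zo;
  NumericVector y(voxo * (long)Cout * N);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout, N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yc = py + voxo * (co + (long)Cout * n);
      for (long t = 0; t < voxo; ++t) yc[t] = b[co];
      for (int c = 0; c < C; ++c) {
        const double *xc = px + vox * (c + (long)C * n);
        for (int dc = 0; dc < 2; ++dc)
          for (int db = 0; db < 2; ++db)
            for (int da = 0; da < 2; ++da) {
              const double wv = w(co, c * 8 + da + 2 * db + 4 * dc);
              if (wv == 0.0) continue;
              for (int k = 0; k < Z; ++k)
                for (int j = 0; j < Y; ++j) {
                  double *dst = yc + da +
                                (long)Xo * ((2 * j + db) +
                                            (long)Yo * (2 * k + dc));
                  const double *src = xc + (long)X * (j + (long)Y * k);
                  for (int i = 0; i < X; ++i) dst[2 * i] += wv * src[i];
                }
            }
      }
    }
  return y;
}

// [[Rcpp::export]]
List upconv3d_bw(NumericVector x, NumericMatrix w, NumericVector gy) {
  int d[5];
  get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Cout = w.nrow();
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const long vox = (long)X * Y * Z, voxo = (long)Xo * Yo * Zo;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericMatrix gw(Cout, C * 8);
  NumericVector gb(Cout);
  const double *px = x.begin(), *pg = gy.begin();
  double *pgx = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *gc = pg + voxo * (co + (long)Cout * n);
      for (long t = 0; t < voxo; ++t) gb[co] += gc[t];
      for (int c = 0; c < C; ++c) {
        const double *xc = px + vox * (c + (long)C * n);
        double *gxc = pgx + vox * (c + (long)C * n);
        for (int dc = 0; dc < 2; ++dc)
          for (int db = 0; db < 2; ++db)
            for (int da = 0; da < 2; ++da) {
              const int wi = c * 8 + da + 2 * db + 4 * dc;
              const double wv = w(co, wi);
              double gwacc = 0.0;
              for (int k = 0; k < Z; ++k)
                for (int j = 0; j < Y; ++j) {
                  const double *gsrc = gc + da +
                                       (long)Xo * ((2 * j + db) +
                                                   (long)Yo * (2 * k + dc));
                  const double *xsrc = xc + (long)X * (j + (long)Y * k);
                  double *gdst = gxc + (long)X * (j + (long)Y * k);
                  for (int i = 0; i < X; ++i) {
                    const double g = gsrc[2 * i];
                    gwacc += g * xsrc[i];
                    gdst[i] += g * wv;
                  }
                }
              gw(co, wi) += gwacc;
            }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
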