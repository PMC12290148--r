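// Native tensor kernels for the segmentation networks.
//
// Tensor layout convention (R side): numeric array with dim c(H, W, C, N),
// column-major, i.e. flat index h + H*(w + W*(c + C*n)).
// Convolution weights: dim c(k, k, Cin, Cout),
// flat index kh + k*(kw + k*(ci + Cin*co)).
//
// All heavy arithmetic runs in single precision (im2col + SGEMM); inputs
// and outputs cross the R boundary as doubles. Single precision is ample
// for these networks and roughly doubles GEMM throughput on one core.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int& H, int& W, int& C,
                            int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline int conv_out_dim(int in, int k, int s, int p, int d) {
  int eff = (k - 1) * d + 1;
  return (in + 2 * p - eff) / s + 1;
}

// Build the im2col matrix for a whole batch.
// cols: (k*k*Cin) x (Ho*Wo*N); column j = ho + Ho*(wo + Wo*n);
// row r = kh + k*kw + k*k*ci.
static void im2col_batch(const double* x, int H, int W, int C, int N, int k,
                         int s, int p, int d, int Ho, int Wo,
                         arma::fmat& cols) {
  const int P = Ho * Wo;
  const size_t K = (size_t)k * k * C;
  cols.set_size(K, (size_t)P * N);
  // column-major fill: each output position writes one contiguous column
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        float* col =
            cols.colptr((size_t)ho + (size_t)Ho * wo + (size_t)P * n);
        const int hi0 = ho * s - p, wi0 = wo * s - p;
        size_t r = 0;
        for (int ci = 0; ci < C; ++ci) {
          const double* xc = xn + (size_t)H * W * ci;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wi0 + kw * d;
            if (wi < 0 || wi >= W) {
              for (int kh = 0; kh < k; ++kh) col[r++] = 0.0f;
            } else {
              const double* xcw = xc + (size_t)H * wi;
              for (int kh = 0; kh < k; ++kh) {
                const int hi = hi0 + kh * d;
                col[r++] = (hi >= 0 && hi < H) ? (float)xcw[hi] : 0.0f;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add a cols-shaped gradient back onto the input grid.
static void col2im_batch(const arma::fmat& gcols, int H, int W, int C, int N,
                         int k, int s, int p, int d, int Ho, int Wo,
                         double* gx) {
  const int P = Ho * Wo;
  std::fill(gx, gx + (size_t)H * W * C * N, 0.0);
  for (int n = 0; n < N; ++n) {
    double* gn = gx + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const float* col =
            gcols.colptr((size_t)ho + (size_t)Ho * wo + (size_t)P * n);
        const int hi0 = ho * s - p, wi0 = wo * s - p;
        size_t r = 0;
        for (int ci = 0; ci < C; ++ci) {
          double* gc = gn + (size_t)H * W * ci;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wi0 + kw * d;
            if (wi < 0 || wi >= W) { r += k; continue; }
            double* gcw = gc + (size_t)H * wi;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = hi0 + kh * d;
              if (hi >= 0 && hi < H) gcw[hi] += (double)col[r];
              ++r;
            }
          }
        }
      }
    }
  }
}

// --- stride-1 convolution via shifted GEMMs --------------------------------
// im2col duplicates the input k^2-fold, which leaves the wide shallow
// levels memory-bound. For stride-1 convolutions the input is instead
// copied once into a zero-padded float buffer and every kernel tap
// contributes one GEMM on a pointer-shifted view of that buffer; reads that
// run past a column land on zeros (or on padded-grid rows that are
// discarded) by construction, so no fix-up pass is needed.

static std::vector<float> ws_xpad, ws_ypad, ws_gzp, ws_gxp;

static void ensure_size(std::vector<float>& v, size_t n) {
  if (v.size() < n) v.resize(n);
}

// per-tap weight slices: Wt9[t] is (Cin x Cout) for tap t = kh + k*kw
static std::vector<arma::fmat> weight_taps(const NumericVector& Wt, int k,
                                           int Cin, int Cout) {
  std::vector<arma::fmat> taps((size_t)k * k);
  for (int t = 0; t < k * k; ++t) {
    taps[t].set_size(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        taps[t](ci, co) = (float)Wt[t + k * k * (ci + (size_t)Cin * co)];
  }
  return taps;
}

// fill the zero-padded buffer for one sample; buffer layout (Hp*Wp, Cin)
// column-major plus `guard` zeroed floats at the end
static void fill_xpad(const double* xn, int H, int W, int Cin, int p,
                      float* xpad, size_t guard) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t total = (size_t)Hp * Wp * Cin + guard;
  std::fill(xpad, xpad + total, 0.0f);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xn + (size_t)H * W * ci;
    float* pc = xpad + (size_t)Hp * Wp * ci;
    for (int w = 0; w < W; ++w) {
      const double* src = xc + (size_t)H * w;
      float* dst = pc + p + (size_t)Hp * (w + p);
      for (int h = 0; h < H; ++h) dst[h] = (float)src[h];
    }
  }
}

// z2 (M x Cout, M = Ho*Wo*N) += conv(x) for stride-1 convolutions
static void conv_fwd_shift(const double* x, int H, int W, int Cin, int N,
                           int k, int p, int d,
                           const std::vector<arma::fmat>& taps, int Cout,
                           int Ho, int Wo, arma::fmat& z2) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t HpWp = (size_t)Hp * Wp;
  const size_t guard = (size_t)(k - 1) * d * (1 + Hp) + 1;
  ensure_size(ws_xpad, HpWp * Cin + guard);
  ensure_size(ws_ypad, HpWp * Cout);
  const int P = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    fill_xpad(x + (size_t)H * W * Cin * n, H, W, Cin, p, ws_xpad.data(),
              guard);
    arma::fmat Y(ws_ypad.data(), HpWp, Cout, false, true);
    Y.zeros();
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const size_t s = (size_t)(kh * d) + (size_t)Hp * (kw * d);
        arma::fmat A(ws_xpad.data() + s, HpWp, Cin, false, true);
        Y += A * taps[kh + k * kw];
      }
    for (int co = 0; co < Cout; ++co) {
      const float* yc = ws_ypad.data() + HpWp * co;
      float* dst = z2.colptr(co) + (size_t)P * n;
      for (int wo = 0; wo < Wo; ++wo) {
        const float* src = yc + (size_t)Hp * wo;
        float* d0 = dst + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) d0[ho] = src[ho];
      }
    }
  }
}

// gW/gx for stride-1 convolutions, given ga (M x Cout)
static void conv_bwd_shift(const double* x, int H, int W, int Cin, int N,
                           int k, int p, int d,
                           const std::vector<arma::fmat>& taps, int Cout,
                           int Ho, int Wo, const arma::fmat& ga,
                           std::vector<arma::fmat>& gtaps, double* gx,
                           bool want_gx, bool want_gw) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t HpWp = (size_t)Hp * Wp;
  const size_t guard = (size_t)(k - 1) * d * (1 + Hp) + 1;
  ensure_size(ws_xpad, HpWp * Cin + guard);
  ensure_size(ws_gzp, guard + HpWp * Cout + guard);
  ensure_size(ws_gxp, HpWp * Cin);
  const int P = Ho * Wo;
  gtaps.assign((size_t)k * k, arma::fmat(Cin, Cout, arma::fill::zeros));
  if (want_gx)
    std::fill(gx, gx + (size_t)H * W * Cin * N, 0.0);
  for (int n = 0; n < N; ++n) {
    if (want_gw)
      fill_xpad(x + (size_t)H * W * Cin * n, H, W, Cin, p, ws_xpad.data(),
                guard);
    std::fill(ws_gzp.begin(),
              ws_gzp.begin() + guard + HpWp * Cout + guard, 0.0f);
    float* gzp = ws_gzp.data() + guard;
    for (int co = 0; co < Cout; ++co) {
      const float* src = ga.colptr(co) + (size_t)P * n;
      float* dst = gzp + HpWp * co;
      for (int wo = 0; wo < Wo; ++wo) {
        const float* s0 = src + (size_t)Ho * wo;
        float* d0 = dst + (size_t)Hp * wo;
        for (int ho = 0; ho < Ho; ++ho) d0[ho] = s0[ho];
      }
    }
    arma::fmat Gz(gzp, HpWp, Cout, false, true);
    if (want_gw)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const size_t s = (size_t)(kh * d) + (size_t)Hp * (kw * d);
          arma::fmat A(ws_xpad.data() + s, HpWp, Cin, false, true);
          gtaps[kh + k * kw] += A.t() * Gz;
        }
    if (want_gx) {
      arma::fmat Gx(ws_gxp.data(), HpWp, Cin, false, true);
      Gx.zeros();
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const size_t s = (size_t)(kh * d) + (size_t)Hp * (kw * d);
          arma::fmat B(gzp - s, HpWp, Cout, false, true);
          Gx += B * taps[kh + k * kw].t();
        }
      double* gn = gx + (size_t)H * W * Cin * n;
      for (int ci = 0; ci < Cin; ++ci) {
        const float* pc = ws_gxp.data() + HpWp * ci;
        double* gc = gn + (size_t)H * W * ci;
        for (int w = 0; w < W; ++w) {
          const float* src = pc + p + (size_t)Hp * (w + p);
          double* dst = gc + (size_t)H * w;
          for (int h = 0; h < H; ++h) dst[h] = (double)src[h];
        }
      }
    }
  }
}

// Fused conv -> batch-norm -> activation forward pass.
// bn_mode: 0 = off, 1 = train (batch stats), 2 = eval (running stats),
//          3 = pass-through (identity, used by linearised test probes).
// act: 0 = none, 1 = ReLU, 2 = leaky ReLU (slope).
// [[Rcpp::export]]
List cpp_conv_unit_fwd(NumericVector x, NumericVector Wt, NumericVector b,
                       int stride, int pad, int dil, int bn_mode,
                       NumericVector gamma, NumericVector beta,
                       NumericVector rmean, NumericVector rvar, double eps,
                       double momentum, int act, double slope) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  if (wd.size() != 4) stop("weights must be a 4-D array (k, k, Cin, Cout)");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("only square kernels are supported");
  if (Cin != C) stop("input has " + std::to_string(C) +
                     " channels but weights expect " + std::to_string(Cin));
  const int Ho = conv_out_dim(H, k, stride, pad, dil);
  const int Wo = conv_out_dim(W, k, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("input too small for this convolution");
  const int P = Ho * Wo;

  const size_t M = (size_t)P * N;
  arma::fmat z2(M, Cout);  // columns contiguous per channel
  if (stride == 1 && k == 1 && pad == 0) {
    // pointwise conv: one GEMM per sample on the (H*W x Cin) view
    arma::fmat W1(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        W1(ci, co) = (float)Wt[ci + (size_t)Cin * co];
    ensure_size(ws_xpad, (size_t)H * W * Cin);
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (size_t)H * W * Cin * n;
      for (size_t i = 0; i < (size_t)H * W * Cin; ++i)
        ws_xpad[i] = (float)xn[i];
      arma::fmat A(ws_xpad.data(), (size_t)H * W, Cin, false, true);
      arma::fmat Yn = A * W1;
      for (int co = 0; co < Cout; ++co)
        std::copy(Yn.colptr(co), Yn.colptr(co) + P,
                  z2.colptr(co) + (size_t)P * n);
    }
  } else if (stride == 1 &&
             (size_t)(H + 2 * pad) * (W + 2 * pad) * 2 <=
                 (size_t)5 * H * W) {
    // padded-grid blowup small: shifted-GEMM path
    std::vector<arma::fmat> taps = weight_taps(Wt, k, Cin, Cout);
    conv_fwd_shift(x.begin(), H, W, Cin, N, k, pad, dil, taps, Cout, Ho, Wo,
                   z2);
  } else {
    arma::fmat cols;
    im2col_batch(x.begin(), H, W, C, N, k, stride, pad, dil, Ho, Wo, cols);
    arma::fmat Wm(k * k * Cin, Cout);
    for (int i = 0; i < k * k * Cin * Cout; ++i)
      Wm.memptr()[i] = (float)Wt[i];
    z2 = cols.t() * Wm;
  }
  for (int co = 0; co < Cout; ++co) z2.col(co) += (float)b[co];

  // z (pre-norm conv output) is needed by the backward pass when BN is on.
  NumericVector z(0);
  if (bn_mode == 1 || bn_mode == 2) {
    z = NumericVector(M * Cout);
    z.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
    double* zp = REAL(z);
    for (int co = 0; co < Cout; ++co) {
      const float* src = z2.colptr(co);
      for (int n = 0; n < N; ++n) {
        double* dst = zp + (size_t)P * (co + (size_t)Cout * n);
        const float* s0 = src + (size_t)P * n;
        for (int j = 0; j < P; ++j) dst[j] = (double)s0[j];
      }
    }
  }

  NumericVector mean_out(Cout), invstd_out(Cout);
  NumericVector rmean_new = clone(rmean), rvar_new = clone(rvar);
  if (bn_mode == 1 || bn_mode == 2) {
    const double m = (double)M;
    for (int co = 0; co < Cout; ++co) {
      double mu, var;
      if (bn_mode == 1) {
        const float* col = z2.colptr(co);
        double s = 0.0, ss = 0.0;
        for (size_t j = 0; j < M; ++j) {
          double v = (double)col[j];
          s += v; ss += v * v;
        }
        mu = s / m;
        var = ss / m - mu * mu;
        if (var < 0) var = 0;
        rmean_new[co] = (1 - momentum) * rmean[co] + momentum * mu;
        // unbiased running variance, matching the usual convention
        double ub = (m > 1) ? var * m / (m - 1) : var;
        rvar_new[co] = (1 - momentum) * rvar[co] + momentum * ub;
      } else {
        mu = rmean[co];
        var = rvar[co];
      }
      const double invstd = 1.0 / std::sqrt(var + eps);
      mean_out[co] = mu;
      invstd_out[co] = invstd;
      float* col = z2.colptr(co);
      const float g = (float)(gamma[co] * invstd);
      const float bb = (float)(beta[co] - gamma[co] * invstd * mu);
      for (size_t j = 0; j < M; ++j) col[j] = col[j] * g + bb;
    }
  } else {
    for (int co = 0; co < Cout; ++co) {
      mean_out[co] = 0.0;
      invstd_out[co] = 1.0;
    }
  }

  if (act == 1) {
    z2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  } else if (act == 2) {
    const float sl = (float)slope;
    z2.transform([sl](float v) { return v > 0.0f ? v : sl * v; });
  }

  NumericVector y(M * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* yp = REAL(y);
  for (int co = 0; co < Cout; ++co) {
    const float* src = z2.colptr(co);
    for (int n = 0; n < N; ++n) {
      double* dst = yp + (size_t)P * (co + (size_t)Cout * n);
      const float* s0 = src + (size_t)P * n;
      for (int j = 0; j < P; ++j) dst[j] = (double)s0[j];
    }
  }

  return List::create(_["y"] = y, _["z"] = z, _["mean"] = mean_out,
                      _["invstd"] = invstd_out, _["rmean"] = rmean_new,
                      _["rvar"] = rvar_new);
}

// Backward pass of the fused unit. Returns gradients w.r.t. input, conv
// weights/bias and BN affine parameters.
// [[Rcpp::export]]
List cpp_conv_unit_bwd(NumericVector x, NumericVector Wt, NumericVector gy,
                       NumericVector y, NumericVector z, NumericVector mean,
                       NumericVector invstd, NumericVector gamma, int stride,
                       int pad, int dil, int bn_mode, int act, double slope,
                       bool want_gx = true, bool want_gw = true) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho, Wo, Cy, Ny;
  get_dim4(gy, Ho, Wo, Cy, Ny);
  if (Cy != Cout || Ny != N) stop("gradient shape mismatch");
  const int P = Ho * Wo;
  const size_t M = (size_t)P * N;

  // ga = dL/d(activation input), as M x Cout (columns contiguous)
  arma::fmat ga(M, Cout);
  const double* gyp = REAL(gy);
  const double* yp = REAL(y);
  for (int co = 0; co < Cout; ++co) {
    float* dst = ga.colptr(co);
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)P * (co + (size_t)Cout * n);
      const double* gsrc = gyp + off;
      const double* ysrc = yp + off;
      float* d0 = dst + (size_t)P * n;
      if (act == 1) {
        for (int j = 0; j < P; ++j)
          d0[j] = ysrc[j] > 0 ? (float)gsrc[j] : 0.0f;
      } else if (act == 2) {
        const float sl = (float)slope;
        for (int j = 0; j < P; ++j)
          d0[j] = ysrc[j] > 0 ? (float)gsrc[j] : sl * (float)gsrc[j];
      } else {
        for (int j = 0; j < P; ++j) d0[j] = (float)gsrc[j];
      }
    }
  }

  // Back through batch norm to gz = dL/d(conv output), in place in ga
  NumericVector ggamma(Cout), gbeta(Cout);
  if (bn_mode == 1 || bn_mode == 2) {
    const double* zp = REAL(z);
    const double m = (double)M;
    for (int co = 0; co < Cout; ++co) {
      const double mu = mean[co], is = invstd[co], gmm = gamma[co];
      float* gcol = ga.colptr(co);
      double sg = 0.0, sgx = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* zsrc = zp + (size_t)P * (co + (size_t)Cout * n);
        const float* g0 = gcol + (size_t)P * n;
        for (int j = 0; j < P; ++j) {
          const double g = (double)g0[j];
          sg += g;
          sgx += g * (zsrc[j] - mu) * is;
        }
      }
      ggamma[co] = sgx;
      gbeta[co] = sg;
      if (bn_mode == 1) {
        const float a1 = (float)(gmm * is);
        const float a2 = (float)(gmm * is * sg / m);
        const float a3 = (float)(gmm * is * sgx / m * is);
        for (int n = 0; n < N; ++n) {
          const double* zsrc = zp + (size_t)P * (co + (size_t)Cout * n);
          float* g0 = gcol + (size_t)P * n;
          for (int j = 0; j < P; ++j)
            g0[j] = a1 * g0[j] - a2 - a3 * (float)(zsrc[j] - mu);
        }
      } else {
        const float a1 = (float)(gmm * is);
        for (size_t j = 0; j < M; ++j) gcol[j] *= a1;
      }
    }
  } else {
    for (int co = 0; co < Cout; ++co) {
      ggamma[co] = 0.0;
      gbeta[co] = 0.0;
    }
  }

  // Conv backward
  NumericVector gW(k * k * Cin * Cout);
  gW.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(ga.col(co));
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);

  if (stride == 1 && k == 1 && pad == 0) {
    arma::fmat W1(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        W1(ci, co) = (float)Wt[ci + (size_t)Cin * co];
    arma::fmat gW1(Cin, Cout, arma::fill::zeros);
    ensure_size(ws_xpad, (size_t)H * W * Cin);
    ensure_size(ws_gxp, (size_t)H * W * Cin);
    double* gxp = REAL(gx);
    for (int n = 0; n < N; ++n) {
      // the n-th row block of ga is contiguous per channel
      arma::fmat Gn((size_t)P, Cout);
      for (int co = 0; co < Cout; ++co)
        std::copy(ga.colptr(co) + (size_t)P * n,
                  ga.colptr(co) + (size_t)P * (n + 1), Gn.colptr(co));
      if (want_gw) {
        const double* xn = x.begin() + (size_t)H * W * Cin * n;
        for (size_t i = 0; i < (size_t)H * W * Cin; ++i)
          ws_xpad[i] = (float)xn[i];
        arma::fmat A(ws_xpad.data(), (size_t)H * W, Cin, false, true);
        gW1 += A.t() * Gn;
      }
      if (want_gx) {
        arma::fmat Gx(ws_gxp.data(), (size_t)H * W, Cin, false, true);
        Gx = Gn * W1.t();
        double* gn = gxp + (size_t)H * W * Cin * n;
        for (size_t i = 0; i < (size_t)H * W * Cin; ++i)
          gn[i] = (double)ws_gxp[i];
      }
    }
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        gW[ci + (size_t)Cin * co] = (double)gW1(ci, co);
  } else if (stride == 1 &&
             (size_t)(H + 2 * pad) * (W + 2 * pad) * 2 <=
                 (size_t)5 * H * W) {
    std::vector<arma::fmat> taps = weight_taps(Wt, k, Cin, Cout);
    std::vector<arma::fmat> gtaps;
    conv_bwd_shift(x.begin(), H, W, Cin, N, k, pad, dil, taps, Cout, Ho, Wo,
                   ga, gtaps, REAL(gx), want_gx, want_gw);
    for (int t = 0; t < k * k; ++t)
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          gW[t + k * k * (ci + (size_t)Cin * co)] = (double)gtaps[t](ci, co);
  } else {
    if (want_gw) {
      arma::fmat cols;
      im2col_batch(x.begin(), H, W, C, N, k, stride, pad, dil, Ho, Wo, cols);
      arma::fmat gWm = cols * ga;  // (k*k*Cin) x Cout
      for (int i = 0; i < k * k * Cin * Cout; ++i)
        gW[i] = (double)gWm.memptr()[i];
    }
    if (want_gx) {
      arma::fmat Wm(k * k * Cin, Cout);
      for (int i = 0; i < k * k * Cin * Cout; ++i)
        Wm.memptr()[i] = (float)Wt[i];
      arma::fmat gcols = Wm * ga.t();  // (k*k*Cin) x M
      col2im_batch(gcols, H, W, C, N, k, stride, pad, dil, Ho, Wo, REAL(gx));
    }
  }

  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb,
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// 2x2 average pooling, stride 2.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("average pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = xp + (size_t)H * W * cn;
    double* ys = yp + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        ys[ho + (size_t)Ho * wo] =
            0.25 * (xs[h + (size_t)H * w] + xs[h + 1 + (size_t)H * w] +
                    xs[h + (size_t)H * (w + 1)] +
                    xs[h + 1 + (size_t)H * (w + 1)]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector gy) {
  int Ho, Wo, C, N;
  get_dim4(gy, Ho, Wo, C, N);
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gs = gp + (size_t)Ho * Wo * cn;
    double* xs = xp + (size_t)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * gs[ho + (size_t)Ho * wo];
        const int h = 2 * ho, w = 2 * wo;
        xs[h + (size_t)H * w] = g;
        xs[h + 1 + (size_t)H * w] = g;
        xs[h + (size_t)H * (w + 1)] = g;
        xs[h + 1 + (size_t)H * (w + 1)] = g;
      }
  }
  return gx;
}

struct LinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w0, w1;
};

// half-pixel-centre source coordinates (the common align_corners = FALSE)
static LinWeights lin_weights(int in, int out) {
  LinWeights lw;
  lw.i0.resize(out); lw.i1.resize(out); lw.w0.resize(out); lw.w1.resize(out);
  const double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int i0 = (int)std::floor(src);
    int i1 = std::min(i0 + 1, in - 1);
    double w1 = src - i0;
    lw.i0[o] = i0; lw.i1[o] = i1; lw.w0[o] = 1.0 - w1; lw.w1[o] = w1;
  }
  return lw;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N;
  get_dim4(x, H, W, C, N);
  LinWeights lh = lin_weights(H, Ho), lwd = lin_weights(W, Wo);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = xp + (size_t)H * W * cn;
    double* ys = yp + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = lwd.i0[wo], w1 = lwd.i1[wo];
      const double a = lwd.w0[wo], bq = lwd.w1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = lh.i0[ho], h1 = lh.i1[ho];
        const double c = lh.w0[ho], d = lh.w1[ho];
        ys[ho + (size_t)Ho * wo] =
            a * (c * xs[h0 + (size_t)H * w0] + d * xs[h1 + (size_t)H * w0]) +
            bq * (c * xs[h0 + (size_t)H * w1] + d * xs[h1 + (size_t)H * w1]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W) {
  int Ho, Wo, C, N;
  get_dim4(gy, Ho, Wo, C, N);
  LinWeights lh = lin_weights(H, Ho), lwd = lin_weights(W, Wo);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gs = gp + (size_t)Ho * Wo * cn;
    double* xs = xp + (size_t)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = lwd.i0[wo], w1 = lwd.i1[wo];
      const double a = lwd.w0[wo], bq = lwd.w1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = lh.i0[ho], h1 = lh.i1[ho];
        const double c = lh.w0[ho], d = lh.w1[ho];
        const double g = gs[ho + (size_t)Ho * wo];
        xs[h0 + (size_t)H * w0] += a * c * g;
        xs[h1 + (size_t)H * w0] += a * d * g;
        xs[h0 + (size_t)H * w1] += bq * c * g;
        xs[h1 + (size_t)H * w1] += bq * d * g;
      }
    }
  }
  return gx;
}

// In-place Adam update: p, m, v are modified directly (they are owned
// exclusively by the layer's parameter environment).
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double b1, double b2,
                     double c1, double c2, double eps) {
  const R_xlen_t n = p.size();
  double* pp = REAL(p);
  const double* gp = REAL(g);
  double* mp = REAL(m);
  double* vp = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}
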