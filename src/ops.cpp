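// Low-level array kernels for the segmentation network.
//
// All feature maps use the internal layout (C, H, W, N), column-major, so a
// feature map is a stack of N contiguous (C, H, W) cubes and every channel
// contraction is a contiguous GEMM. Convolutions are stride-1 with "same"
// padding pad = dilation*(k-1)/2; downsampling is done by the pooling ops.
// Convolution weights use layout (Co, Ci, k, k) so the (kh, kw) tap is a
// contiguous (Co, Ci) matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array");
  return d;
}

// ---------------------------------------------------------------- conv2d ----

// Convolutions run in single precision: inputs, weights and gradients are
// converted to float, the per-tap (Co, Ci) GEMMs accumulate in float, and
// results are returned as double. This halves memory traffic and doubles
// GEMM throughput on one core at ~1e-7 relative arithmetic error.

using arma::fcube;
using arma::fmat;

static fcube to_fcube(const double* p, size_t a, size_t b, size_t c) {
  fcube out(a, b, c);
  float* o = out.memptr();
  const size_t n = a * b * c;
  for (size_t i = 0; i < n; ++i) o[i] = (float)p[i];
  return out;
}

static fmat to_fmat(const double* p, size_t a, size_t b) {
  fmat out(a, b);
  float* o = out.memptr();
  const size_t n = a * b;
  for (size_t i = 0; i < n; ++i) o[i] = (float)p[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(const NumericVector& x, const NumericVector& w,
                            const NumericVector& b, int dilation) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  const int Ci = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Co = wd[0], k = wd[2];
  if (wd[1] != Ci)
    stop("conv2d: input has %d channels but weights expect %d", Ci, wd[1]);
  if (wd[3] != k || (k != 1 && k != 3)) stop("conv2d: kernel must be 1 or 3");
  const int d = dilation, c0 = (k - 1) / 2;

  NumericVector out((R_xlen_t)Co * H * W * N);
  out.attr("dim") = IntegerVector::create(Co, H, W, N);
  double* op = REAL(out);

  const fmat Wf = to_fmat(REAL(w), Co, (size_t)Ci * k * k);
  const arma::fvec bf = arma::conv_to<arma::fvec>::from(
      arma::vec(const_cast<double*>(REAL(b)), Co, false));

  if (k == 1) {
    const fcube xf = to_fcube(REAL(x), Ci, (size_t)H * W, N);
    const fmat xm(const_cast<float*>(xf.memptr()), Ci, (size_t)H * W * N, false);
    fmat ym = Wf * xm;
    ym.each_col() += bf;
    const float* yp = ym.memptr();
    const R_xlen_t tot = out.size();
    for (R_xlen_t i = 0; i < tot; ++i) op[i] = yp[i];
    return out;
  }

  for (int n = 0; n < N; ++n) {
    fcube xc = to_fcube(REAL(x) + (size_t)n * Ci * H * W, Ci, H, W);
    fcube yc(Co, H, W);
    yc.each_slice() = arma::repmat(bf, 1, H);
    for (int kh = 0; kh < k; ++kh) {
      for (int kw = 0; kw < k; ++kw) {
        const int oh = d * (kh - c0), ow = d * (kw - c0);
        const int hs = std::max(0, -oh), he = H - 1 - std::max(0, oh);
        const int ws = std::max(0, -ow), we = W - 1 - std::max(0, ow);
        if (hs > he || ws > we) continue;
        const int Hv = he - hs + 1, Wv = we - ws + 1;
        fcube xs = xc.subcube(0, hs + oh, ws + ow, Ci - 1, he + oh, we + ow);
        fmat xm(xs.memptr(), Ci, (size_t)Hv * Wv, false);
        const fmat Wk(const_cast<float*>(Wf.memptr()) + (size_t)Co * Ci * (kh + k * kw),
                      Co, Ci, false);
        fmat g = Wk * xm;
        fcube gc(g.memptr(), Co, Hv, Wv, false);
        yc.subcube(0, hs, ws, Co - 1, he, we) += gc;
      }
    }
    const float* yp = yc.memptr();
    double* od = op + (size_t)n * Co * H * W;
    const size_t m = (size_t)Co * H * W;
    for (size_t i = 0; i < m; ++i) od[i] = yp[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const NumericVector& x, const NumericVector& w,
                   const NumericVector& gout, int dilation, bool want_gx) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  const int Ci = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Co = wd[0], k = wd[2];
  const int d = dilation, c0 = (k - 1) / 2;

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);
  const double* gp = REAL(gout);

  const R_xlen_t tot = gout.size();
  for (R_xlen_t i = 0; i < tot; ++i) gbp[i % Co] += gp[i];

  const fmat Wf = to_fmat(REAL(w), Co, (size_t)Ci * k * k);
  fmat gWf((size_t)Co, (size_t)Ci * k * k, arma::fill::zeros);

  NumericVector gx;
  if (want_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = xd;
  }

  if (k == 1) {
    const fcube xf = to_fcube(REAL(x), Ci, (size_t)H * W, N);
    const fcube gf = to_fcube(gp, Co, (size_t)H * W, N);
    const fmat xm(const_cast<float*>(xf.memptr()), Ci, (size_t)H * W * N, false);
    const fmat gym(const_cast<float*>(gf.memptr()), Co, (size_t)H * W * N, false);
    gWf = gym * xm.t();
    if (want_gx) {
      fmat gxm = Wf.t() * gym;
      const float* q = gxm.memptr();
      double* gxp = REAL(gx);
      const R_xlen_t nx = gx.size();
      for (R_xlen_t i = 0; i < nx; ++i) gxp[i] = q[i];
    }
  } else {
    for (int n = 0; n < N; ++n) {
      fcube xc = to_fcube(REAL(x) + (size_t)n * Ci * H * W, Ci, H, W);
      fcube gyc = to_fcube(gp + (size_t)n * Co * H * W, Co, H, W);
      fcube gxc;
      if (want_gx) gxc.zeros(Ci, H, W);
      for (int kh = 0; kh < k; ++kh) {
        for (int kw = 0; kw < k; ++kw) {
          const int oh = d * (kh - c0), ow = d * (kw - c0);
          const int hs = std::max(0, -oh), he = H - 1 - std::max(0, oh);
          const int ws = std::max(0, -ow), we = W - 1 - std::max(0, ow);
          if (hs > he || ws > we) continue;
          const int Hv = he - hs + 1, Wv = we - ws + 1;
          fcube gys = gyc.subcube(0, hs, ws, Co - 1, he, we);
          fmat gym(gys.memptr(), Co, (size_t)Hv * Wv, false);
          fcube xs = xc.subcube(0, hs + oh, ws + ow, Ci - 1, he + oh, we + ow);
          fmat xm(xs.memptr(), Ci, (size_t)Hv * Wv, false);
          fmat gWk(gWf.memptr() + (size_t)Co * Ci * (kh + k * kw), Co, Ci,
                   false, true);
          gWk += gym * xm.t();
          if (want_gx) {
            const fmat Wk(const_cast<float*>(Wf.memptr()) +
                          (size_t)Co * Ci * (kh + k * kw), Co, Ci, false);
            fmat gxm = Wk.t() * gym;
            fcube gxs(gxm.memptr(), Ci, Hv, Wv, false);
            gxc.subcube(0, hs + oh, ws + ow, Ci - 1, he + oh, we + ow) += gxs;
          }
        }
      }
      if (want_gx) {
        const float* q = gxc.memptr();
        double* gxp = REAL(gx) + (size_t)n * Ci * H * W;
        const size_t m = (size_t)Ci * H * W;
        for (size_t i = 0; i < m; ++i) gxp[i] += q[i];
      }
    }
  }
  {
    const float* q = gWf.memptr();
    const R_xlen_t nw = gw.size();
    for (R_xlen_t i = 0; i < nw; ++i) gwp[i] = q[i];
  }
  if (want_gx) {
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------- depthwise 3x3 convolution ----

// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(const NumericVector& x, const NumericVector& w,
                            const NumericVector& b) {
  IntegerVector xd = dims4(x);
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 3 || wd[0] != C || wd[1] != 3 || wd[2] != 3)
    stop("dwconv: weights must be (C, 3, 3) with C matching the input");
  NumericVector out(x.size());
  out.attr("dim") = xd;
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  double* op = REAL(out);

  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * C * H * W;
    for (int wq = 0; wq < W; ++wq) {
      for (int h = 0; h < H; ++h) {
        double* orow = op + base + (size_t)C * (h + (size_t)H * wq);
        for (int c = 0; c < C; ++c) orow[c] = bp[c];
        for (int kh = 0; kh < 3; ++kh) {
          const int hh = h + kh - 1;
          if (hh < 0 || hh >= H) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int ww = wq + kw - 1;
            if (ww < 0 || ww >= W) continue;
            const double* xrow = xp + base + (size_t)C * (hh + (size_t)H * ww);
            const double* wrow = wp + (size_t)C * (kh + 3 * kw);
            for (int c = 0; c < C; ++c) orow[c] += wrow[c] * xrow[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(const NumericVector& x, const NumericVector& w,
                   const NumericVector& gout) {
  IntegerVector xd = dims4(x);
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(C);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(gout);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);

  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * C * H * W;
    for (int wq = 0; wq < W; ++wq) {
      for (int h = 0; h < H; ++h) {
        const double* grow = gp + base + (size_t)C * (h + (size_t)H * wq);
        for (int c = 0; c < C; ++c) gbp[c] += grow[c];
        for (int kh = 0; kh < 3; ++kh) {
          const int hh = h + kh - 1;
          if (hh < 0 || hh >= H) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int ww = wq + kw - 1;
            if (ww < 0 || ww >= W) continue;
            const size_t xoff = base + (size_t)C * (hh + (size_t)H * ww);
            const size_t woff = (size_t)C * (kh + 3 * kw);
            for (int c = 0; c < C; ++c) {
              gwp[woff + c] += grow[c] * xp[xoff + c];
              gxp[xoff + c] += grow[c] * wp[woff + c];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// --------------------------------------------------------------- pooling ----

// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericVector& x, int k, int stride, int pad) {
  IntegerVector xd = dims4(x);
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)C * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  IntegerVector amax(out.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ap = INTEGER(amax);

  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * C * H * W;
    const size_t ob = (size_t)n * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t ooff = ob + (size_t)C * (ho + (size_t)Ho * wo);
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int wq = wo * stride - pad + kw;
              if (wq < 0 || wq >= W) continue;
              const size_t xi = xb + c + (size_t)C * (h + (size_t)H * wq);
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          }
          op[ooff + c] = best;
          ap[ooff + c] = (int)bi;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(const NumericVector& gout, const IntegerVector& amax,
                             const IntegerVector& xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  const double* gp = REAL(gout);
  const int* ap = INTEGER(amax);
  double* gxp = REAL(gx);
  const R_xlen_t tot = gout.size();
  for (R_xlen_t i = 0; i < tot; ++i) gxp[ap[i]] += gp[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(const NumericVector& x) {
  IntegerVector xd = dims4(x);
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("avgpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)C * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * C * H * W, ob = (size_t)n * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t o = ob + (size_t)C * (ho + (size_t)Ho * wo);
        const size_t i00 = xb + (size_t)C * (2 * ho + (size_t)H * (2 * wo));
        const size_t i10 = i00 + C;                    // h+1
        const size_t i01 = i00 + (size_t)C * H;        // w+1
        const size_t i11 = i01 + C;
        for (int c = 0; c < C; ++c)
          op[o + c] = 0.25 * (xp[i00 + c] + xp[i10 + c] + xp[i01 + c] + xp[i11 + c]);
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(const NumericVector& gout, const IntegerVector& xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx((R_xlen_t)C * H * W * N);
  gx.attr("dim") = xdim;
  const double* gp = REAL(gout);
  double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * C * H * W, ob = (size_t)n * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t o = ob + (size_t)C * (ho + (size_t)Ho * wo);
        const size_t i00 = xb + (size_t)C * (2 * ho + (size_t)H * (2 * wo));
        const size_t i10 = i00 + C, i01 = i00 + (size_t)C * H, i11 = i01 + C;
        for (int c = 0; c < C; ++c) {
          const double g = 0.25 * gp[o + c];
          gxp[i00 + c] += g; gxp[i10 + c] += g;
          gxp[i01 + c] += g; gxp[i11 + c] += g;
        }
      }
  }
  return gx;
}

// ----------------------------------------------------- bilinear resampling ----

// Half-pixel-center source coordinate for output index i at scale Hin/Hout.
static inline void src_weights(int i, int Hin, int Hout, int& i0, int& i1, double& w1) {
  double s = (i + 0.5) * ((double)Hin / Hout) - 0.5;
  if (s < 0) s = 0;
  if (s > Hin - 1) s = Hin - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, Hin - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(const NumericVector& x, int Ho, int Wo) {
  IntegerVector xd = dims4(x);
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> hf(Ho), wf(Wo);
  for (int i = 0; i < Ho; ++i) src_weights(i, H, Ho, h0[i], h1[i], hf[i]);
  for (int j = 0; j < Wo; ++j) src_weights(j, W, Wo, w0[j], w1[j], wf[j]);
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * C * H * W, ob = (size_t)n * C * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const size_t o = ob + (size_t)C * (i + (size_t)Ho * j);
        const size_t a00 = xb + (size_t)C * (h0[i] + (size_t)H * w0[j]);
        const size_t a10 = xb + (size_t)C * (h1[i] + (size_t)H * w0[j]);
        const size_t a01 = xb + (size_t)C * (h0[i] + (size_t)H * w1[j]);
        const size_t a11 = xb + (size_t)C * (h1[i] + (size_t)H * w1[j]);
        const double fh = hf[i], fw = wf[j];
        const double c00 = (1 - fh) * (1 - fw), c10 = fh * (1 - fw);
        const double c01 = (1 - fh) * fw, c11 = fh * fw;
        for (int c = 0; c < C; ++c)
          op[o + c] = c00 * xp[a00 + c] + c10 * xp[a10 + c] +
                      c01 * xp[a01 + c] + c11 * xp[a11 + c];
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(const NumericVector& gout, const IntegerVector& xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  IntegerVector gd = dims4(gout);
  const int Ho = gd[1], Wo = gd[2];
  NumericVector gx((R_xlen_t)C * H * W * N);
  gx.attr("dim") = xdim;
  const double* gp = REAL(gout);
  double* gxp = REAL(gx);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> hf(Ho), wf(Wo);
  for (int i = 0; i < Ho; ++i) src_weights(i, H, Ho, h0[i], h1[i], hf[i]);
  for (int j = 0; j < Wo; ++j) src_weights(j, W, Wo, w0[j], w1[j], wf[j]);
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * C * H * W, ob = (size_t)n * C * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const size_t o = ob + (size_t)C * (i + (size_t)Ho * j);
        const size_t a00 = xb + (size_t)C * (h0[i] + (size_t)H * w0[j]);
        const size_t a10 = xb + (size_t)C * (h1[i] + (size_t)H * w0[j]);
        const size_t a01 = xb + (size_t)C * (h0[i] + (size_t)H * w1[j]);
        const size_t a11 = xb + (size_t)C * (h1[i] + (size_t)H * w1[j]);
        const double fh = hf[i], fw = wf[j];
        const double c00 = (1 - fh) * (1 - fw), c10 = fh * (1 - fw);
        const double c01 = (1 - fh) * fw, c11 = fh * fw;
        for (int c = 0; c < C; ++c) {
          const double g = gp[o + c];
          gxp[a00 + c] += c00 * g; gxp[a10 + c] += c10 * g;
          gxp[a01 + c] += c01 * g; gxp[a11 + c] += c11 * g;
        }
      }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_resize_nearest(const NumericVector& x, int Ho, int Wo) {
  IntegerVector xd = dims4(x);
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  std::vector<int> hi(Ho), wi(Wo);
  for (int i = 0; i < Ho; ++i)
    hi[i] = std::min(H - 1, (int)std::floor((i + 0.5) * ((double)H / Ho)));
  for (int j = 0; j < Wo; ++j)
    wi[j] = std::min(W - 1, (int)std::floor((j + 0.5) * ((double)W / Wo)));
  for (int n = 0; n < N; ++n) {
    const size_t xb = (size_t)n * C * H * W, ob = (size_t)n * C * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const size_t o = ob + (size_t)C * (i + (size_t)Ho * j);
        const size_t a = xb + (size_t)C * (hi[i] + (size_t)H * wi[j]);
        for (int c = 0; c < C; ++c) op[o + c] = xp[a + c];
      }
  }
  return out;
}

// ------------------------------------------------------ elementwise ops ----

// [[Rcpp::export]]
NumericVector cpp_relu_fw(const NumericVector& x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); double* op = REAL(out);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(const NumericVector& out, const NumericVector& g) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double* op = REAL(out); const double* gp = REAL(g);
  double* xp = REAL(gx);
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = op[i] > 0 ? gp[i] : 0.0;
  return gx;
}

static inline double norm_cdf(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }
static inline double norm_pdf(double x) {
  return 0.3989422804014326779 * std::exp(-0.5 * x * x);
}

// [[Rcpp::export]]
NumericVector cpp_gelu_fw(const NumericVector& x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); double* op = REAL(out);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] * norm_cdf(xp[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bw(const NumericVector& x, const NumericVector& g) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double* xp = REAL(x); const double* gp = REAL(g);
  double* op = REAL(gx);
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    op[i] = gp[i] * (norm_cdf(xp[i]) + xp[i] * norm_pdf(xp[i]));
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_fw(const NumericVector& x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); double* op = REAL(out);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return out;
}

// ------------------------------------------- layer norm over channels ----

// [[Rcpp::export]]
List cpp_ln_fw(const NumericVector& x, const NumericVector& gamma,
               const NumericVector& beta, double eps) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t K = x.size() / C;
  NumericVector out(x.size());
  out.attr("dim") = xd;
  NumericVector mu(K), invstd(K);
  const double* xp = REAL(x);
  const double* gp = REAL(gamma);
  const double* bp = REAL(beta);
  double* op = REAL(out);
  double* mp = REAL(mu);
  double* ip = REAL(invstd);
  for (R_xlen_t k = 0; k < K; ++k) {
    const double* col = xp + k * C;
    double s = 0, s2 = 0;
    for (int c = 0; c < C; ++c) { s += col[c]; s2 += col[c] * col[c]; }
    const double m = s / C;
    double v = s2 / C - m * m;
    if (v < 0) v = 0;
    const double is = 1.0 / std::sqrt(v + eps);
    mp[k] = m; ip[k] = is;
    double* oc = op + k * C;
    for (int c = 0; c < C; ++c) oc[c] = gp[c] * (col[c] - m) * is + bp[c];
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_ln_bw(const NumericVector& x, const NumericVector& gamma,
               const NumericVector& mu, const NumericVector& invstd,
               const NumericVector& gout) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t K = x.size() / C;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gamma);
  const double* mp = REAL(mu);
  const double* ip = REAL(invstd);
  const double* op = REAL(gout);
  double* gxp = REAL(gx);
  double* dgp = REAL(dgamma);
  double* dbp = REAL(dbeta);
  for (R_xlen_t k = 0; k < K; ++k) {
    const double* col = xp + k * C;
    const double* gcol = op + k * C;
    double* gxc = gxp + k * C;
    const double m = mp[k], is = ip[k];
    double s1 = 0, s2 = 0;
    for (int c = 0; c < C; ++c) {
      const double xh = (col[c] - m) * is;
      const double dxh = gcol[c] * gp[c];
      dgp[c] += gcol[c] * xh;
      dbp[c] += gcol[c];
      s1 += dxh;
      s2 += dxh * xh;
    }
    s1 /= C; s2 /= C;
    for (int c = 0; c < C; ++c) {
      const double xh = (col[c] - m) * is;
      const double dxh = gcol[c] * gp[c];
      gxc[c] = is * (dxh - s1 - xh * s2);
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ------------------------------------------------------- batch norm ----

// [[Rcpp::export]]
List cpp_bn_stats(const NumericVector& x) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t K = x.size() / C;
  NumericVector mu(C), var(C);
  double* mp = REAL(mu);
  double* vp = REAL(var);
  const double* xp = REAL(x);
  for (R_xlen_t i = 0; i < (R_xlen_t)K; ++i) {
    const double* col = xp + i * C;
    for (int c = 0; c < C; ++c) {
      mp[c] += col[c];
      vp[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mp[c] /= K;
    vp[c] = vp[c] / K - mp[c] * mp[c];
    if (vp[c] < 0) vp[c] = 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_apply(const NumericVector& x, const NumericVector& gamma,
                           const NumericVector& beta, const NumericVector& mu,
                           const NumericVector& invstd) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t K = x.size() / C;
  NumericVector out(x.size());
  out.attr("dim") = xd;
  const double* xp = REAL(x);
  double* op = REAL(out);
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = REAL(gamma)[c] * REAL(invstd)[c];
    b[c] = REAL(beta)[c] - a[c] * REAL(mu)[c];
  }
  for (R_xlen_t i = 0; i < (R_xlen_t)K; ++i) {
    const double* col = xp + i * C;
    double* oc = op + i * C;
    for (int c = 0; c < C; ++c) oc[c] = a[c] * col[c] + b[c];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bn_bw(const NumericVector& x, const NumericVector& gamma,
               const NumericVector& mu, const NumericVector& invstd,
               const NumericVector& gout, bool train) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t K = x.size() / C;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gout);
  const double* gm = REAL(gamma);
  const double* mp = REAL(mu);
  const double* ip = REAL(invstd);
  double* gxp = REAL(gx);
  double* dgp = REAL(dgamma);
  double* dbp = REAL(dbeta);
  for (R_xlen_t i = 0; i < (R_xlen_t)K; ++i) {
    const double* col = xp + i * C;
    const double* gcol = gp + i * C;
    for (int c = 0; c < C; ++c) {
      dgp[c] += gcol[c] * (col[c] - mp[c]) * ip[c];
      dbp[c] += gcol[c];
    }
  }
  if (train) {
    std::vector<double> mdb(C), mdg(C);
    for (int c = 0; c < C; ++c) { mdb[c] = dbp[c] / K; mdg[c] = dgp[c] / K; }
    for (R_xlen_t i = 0; i < (R_xlen_t)K; ++i) {
      const double* col = xp + i * C;
      const double* gcol = gp + i * C;
      double* gxc = gxp + i * C;
      for (int c = 0; c < C; ++c) {
        const double xh = (col[c] - mp[c]) * ip[c];
        gxc[c] = ip[c] * gm[c] * (gcol[c] - mdb[c] - xh * mdg[c]);
      }
    }
  } else {
    for (R_xlen_t i = 0; i < (R_xlen_t)K; ++i) {
      const double* gcol = gp + i * C;
      double* gxc = gxp + i * C;
      for (int c = 0; c < C; ++c) gxc[c] = gcol[c] * gm[c] * ip[c];
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ----------------------------------- fused conv + batch norm + activation ----

// y = act(a * z + s) per channel, one pass; a = gamma*invstd, s = beta - a*mu.
// [[Rcpp::export]]
NumericVector cpp_affine_act(const NumericVector& z, const NumericVector& a,
                             const NumericVector& s, bool relu) {
  IntegerVector zd = dims4(z);
  const int C = zd[0];
  const R_xlen_t K = z.size() / C;
  NumericVector out(z.size());
  out.attr("dim") = zd;
  const double* zp = REAL(z);
  const double* ap = REAL(a);
  const double* sp = REAL(s);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < K; ++i) {
    const double* zc = zp + i * C;
    double* oc = op + i * C;
    if (relu) {
      for (int c = 0; c < C; ++c) {
        const double v = ap[c] * zc[c] + sp[c];
        oc[c] = v > 0 ? v : 0.0;
      }
    } else {
      for (int c = 0; c < C; ++c) oc[c] = ap[c] * zc[c] + sp[c];
    }
  }
  return out;
}

// Backward through act + batch norm + conv in one call. z is the conv output
// (pre-norm), x the conv input. Returns gx (optional), gw, gb, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_cbr_bw(const NumericVector& g, const NumericVector& z,
                const NumericVector& x, const NumericVector& w,
                const NumericVector& gamma, const NumericVector& mu,
                const NumericVector& invstd, const NumericVector& a,
                const NumericVector& s, int dilation, bool train, bool relu,
                bool want_gx) {
  IntegerVector zd = dims4(z);
  const int C = zd[0];
  const R_xlen_t K = z.size() / C;
  NumericVector dz(z.size());
  dz.attr("dim") = zd;
  NumericVector dgamma(C), dbeta(C);
  const double* gp = REAL(g);
  const double* zp = REAL(z);
  const double* ap = REAL(a);
  const double* sp = REAL(s);
  const double* mp = REAL(mu);
  const double* ip = REAL(invstd);
  const double* gmp = REAL(gamma);
  double* dzp = REAL(dz);
  double* dgp = REAL(dgamma);
  double* dbp = REAL(dbeta);

  // pass 1: activation mask, per-channel reductions; stash g1 in dz
  for (R_xlen_t i = 0; i < K; ++i) {
    const double* zc = zp + i * C;
    const double* gc = gp + i * C;
    double* dc = dzp + i * C;
    for (int c = 0; c < C; ++c) {
      double g1 = gc[c];
      if (relu && (ap[c] * zc[c] + sp[c]) <= 0) g1 = 0.0;
      dc[c] = g1;
      dgp[c] += g1 * (zc[c] - mp[c]) * ip[c];
      dbp[c] += g1;
    }
  }
  // pass 2: batch-norm input gradient
  if (train) {
    std::vector<double> mdb(C), mdg(C);
    for (int c = 0; c < C; ++c) { mdb[c] = dbp[c] / K; mdg[c] = dgp[c] / K; }
    for (R_xlen_t i = 0; i < K; ++i) {
      const double* zc = zp + i * C;
      double* dc = dzp + i * C;
      for (int c = 0; c < C; ++c) {
        const double xh = (zc[c] - mp[c]) * ip[c];
        dc[c] = ip[c] * gmp[c] * (dc[c] - mdb[c] - xh * mdg[c]);
      }
    }
  } else {
    for (R_xlen_t i = 0; i < K; ++i) {
      double* dc = dzp + i * C;
      for (int c = 0; c < C; ++c) dc[c] *= gmp[c] * ip[c];
    }
  }
  List conv = cpp_conv2d_bw(x, w, dz, dilation, want_gx);
  return List::create(_["gx"] = conv["gx"], _["gw"] = conv["gw"],
                      _["gb"] = conv["gb"], _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ------------------------------------------------------------------ adam ----

// In-place update of the private m/v moments; returns the new value vector.
// [[Rcpp::export]]
NumericVector cpp_adam_update(const NumericVector& val, const NumericVector& grad,
                              NumericVector m, NumericVector v, double lr,
                              double beta1, double beta2, double bc1,
                              double bc2, double eps) {
  NumericVector out(val.size());
  out.attr("dim") = val.attr("dim");
  const double* vp = REAL(val);
  const double* gp = REAL(grad);
  double* mp = REAL(m);
  double* vv = REAL(v);
  double* op = REAL(out);
  const R_xlen_t n = val.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vv[i] = beta2 * vv[i] + (1 - beta2) * gp[i] * gp[i];
    op[i] = vp[i] - lr * (mp[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
  return out;
}

// ------------------------------------------------- channel concat / gate ----

// [[Rcpp::export]]
NumericVector cpp_concat2(const NumericVector& a, const NumericVector& b) {
  IntegerVector ad = dims4(a), bd = dims4(b);
  const int Ca = ad[0], Cb = bd[0];
  const R_xlen_t K = a.size() / Ca;
  if (b.size() / Cb != K || ad[1] != bd[1] || ad[2] != bd[2] || ad[3] != bd[3])
    stop("concat: spatial/batch dims differ");
  NumericVector out((R_xlen_t)(Ca + Cb) * K);
  out.attr("dim") = IntegerVector::create(Ca + Cb, ad[1], ad[2], ad[3]);
  const double* ap = REAL(a);
  const double* bp = REAL(b);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < K; ++i) {
    std::memcpy(op + i * (Ca + Cb), ap + i * Ca, Ca * sizeof(double));
    std::memcpy(op + i * (Ca + Cb) + Ca, bp + i * Cb, Cb * sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_split2(const NumericVector& g, int Ca, int Cb) {
  IntegerVector gd = dims4(g);
  const R_xlen_t K = g.size() / (Ca + Cb);
  NumericVector a((R_xlen_t)Ca * K), b((R_xlen_t)Cb * K);
  a.attr("dim") = IntegerVector::create(Ca, gd[1], gd[2], gd[3]);
  b.attr("dim") = IntegerVector::create(Cb, gd[1], gd[2], gd[3]);
  const double* gp = REAL(g);
  double* ap = REAL(a);
  double* bp = REAL(b);
  for (R_xlen_t i = 0; i < K; ++i) {
    std::memcpy(ap + i * Ca, gp + i * (Ca + Cb), Ca * sizeof(double));
    std::memcpy(bp + i * Cb, gp + i * (Ca + Cb) + Ca, Cb * sizeof(double));
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// x: (C,H,W,N) scaled per (channel, sample) by gate (C,N).
// [[Rcpp::export]]
NumericVector cpp_scale_channels_fw(const NumericVector& x, const NumericVector& gate) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t HW = (R_xlen_t)xd[1] * xd[2];
  const int N = xd[3];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  const double* xp = REAL(x);
  const double* gp = REAL(gate);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* gn = gp + (size_t)n * C;
    const double* xn = xp + (size_t)n * C * HW;
    double* on = op + (size_t)n * C * HW;
    for (R_xlen_t i = 0; i < HW; ++i)
      for (int c = 0; c < C; ++c) on[i * C + c] = xn[i * C + c] * gn[c];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_scale_channels_bw(const NumericVector& x, const NumericVector& gate,
                           const NumericVector& g) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t HW = (R_xlen_t)xd[1] * xd[2];
  const int N = xd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gg((R_xlen_t)C * N);
  gg.attr("dim") = IntegerVector::create(C, N);
  const double* xp = REAL(x);
  const double* gp = REAL(gate);
  const double* go = REAL(g);
  double* gxp = REAL(gx);
  double* ggp = REAL(gg);
  for (int n = 0; n < N; ++n) {
    const double* gn = gp + (size_t)n * C;
    const double* xn = xp + (size_t)n * C * HW;
    const double* gon = go + (size_t)n * C * HW;
    double* gxn = gxp + (size_t)n * C * HW;
    double* ggn = ggp + (size_t)n * C;
    for (R_xlen_t i = 0; i < HW; ++i) {
      for (int c = 0; c < C; ++c) {
        gxn[i * C + c] = gon[i * C + c] * gn[c];
        ggn[c] += gon[i * C + c] * xn[i * C + c];
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg);
}

// Global average pool to (C, N).
// [[Rcpp::export]]
NumericVector cpp_gap_fw(const NumericVector& x) {
  IntegerVector xd = dims4(x);
  const int C = xd[0];
  const R_xlen_t HW = (R_xlen_t)xd[1] * xd[2];
  const int N = xd[3];
  NumericVector out((R_xlen_t)C * N);
  out.attr("dim") = IntegerVector::create(C, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * HW;
    double* on = op + (size_t)n * C;
    for (R_xlen_t i = 0; i < HW; ++i)
      for (int c = 0; c < C; ++c) on[c] += xn[i * C + c];
    for (int c = 0; c < C; ++c) on[c] /= HW;
  }
  return out;
}
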