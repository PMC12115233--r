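// Low-level convolution kernels for the CPU detector.
// Tensor layout throughout: column-major R arrays dim = c(H, W, C, N).
// Weight layout: dim = c(kh, kw, Cin, Cout); depthwise: c(kh, kw, C).
// im2col + GEMM (BLAS via Armadillo) for the standard convolution; direct
// loops for the depthwise case where the GEMM would be rank-deficient.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill the im2col matrix M (kh*kw*Cin x Ho*Wo) for image n.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int ph, int pw,
                   int Ho, int Wo, arma::mat& M) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* mcol = M.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * s - pw + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * s - ph + ki;
            const int r = ki + kh * (kj + kw * c);
            mcol[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
              ? xc[hi + (size_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of dM (kh*kw*Cin x Ho*Wo) back onto the input gradient.
static void col2im(const arma::mat& dM, double* dx, int H, int W, int C,
                   int kh, int kw, int s, int ph, int pw, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* mcol = dM.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* dxc = dx + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * s - pw + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * s - ph + ki;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += mcol[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, ph), Wo = out_size(W, kw, stride, pw);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, M);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    Y = M.t() * Wmat;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector dy, NumericVector x, NumericVector w,
                int stride, int ph, int pw, bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0), dw(w.size()), db(Cout);
  if (need_dx) dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat dWmat(dw.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::mat M((size_t)kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, M);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    dWmat += M * dY;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
    if (need_dx) {
      arma::mat dM = Wmat * dY.t();
      col2im(dM, dx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".dwconv_fwd")]]
NumericVector dwconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv: input has %d channels but kernel expects %d", C, wd[2]);
  const int Ho = out_size(H, kh, stride, ph), Wo = out_size(W, kw, stride, pw);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b[c];
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pw + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - ph + ki;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi] * wc[ki + kh * kj];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dwconv_bwd")]]
List dwconv_bwd(NumericVector dy, NumericVector x, NumericVector w,
                int stride, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size()), dw(w.size()), db(C);
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyc[ho + (size_t)Ho * wo];
          db[c] += g;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pw + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - ph + ki;
              if (hi < 0 || hi >= H) continue;
              dwc[ki + kh * kj] += g * xc[hi + (size_t)H * wi];
              dxc[hi + (size_t)H * wi] += g * wc[ki + kh * kj];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// y = x * a[ch] + b[ch], channel = (idx / (H*W)) % C for layout (H,W,C,N).
// [[Rcpp::export(name = ".ch_affine")]]
NumericVector ch_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* px = x.begin(); double* py = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (size_t j = 0; j < hw; ++j, ++i) py[i] = px[i] * ac + bc;
    }
  }
  return y;
}

// z = x * a[ch] + y * b[ch] + c[ch]  (same layout rules as ch_affine)
// [[Rcpp::export(name = ".ch_affine2")]]
NumericVector ch_affine2(NumericVector x, NumericVector y,
                         NumericVector a, NumericVector b, NumericVector cc) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2];
  NumericVector z(x.size());
  z.attr("dim") = xd;
  const double* px = x.begin(); const double* py = y.begin(); double* pz = z.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], ccc = cc[c];
      for (size_t j = 0; j < hw; ++j, ++i) pz[i] = px[i] * ac + py[i] * bc + ccc;
    }
  }
  return z;
}

// SiLU x*sigmoid(x); returns y with the sigmoid attached as attribute "s".
// [[Rcpp::export(name = ".silu_fwd_cpp")]]
List silu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double sg = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = sg; y[i] = x[i] * sg;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["s"] = s);
}

// dx = dy * s * (1 + x * (1 - s))
// [[Rcpp::export(name = ".silu_bwd_cpp")]]
NumericVector silu_bwd_cpp(NumericVector dy, NumericVector x, NumericVector s) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    dx[i] = dy[i] * (s[i] * (1.0 + x[i] * (1.0 - s[i])));
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
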