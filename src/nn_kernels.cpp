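// Numerical kernels for the segmentation network.
//
// Feature-map layout: column-major R arrays dim = c(C, H, W) for a single
// map and c(C, H, W, N) for a batch, i.e. channel index varies fastest.
// Convolutions use im2col + GEMM; the column matrix has K = C*kh*kw rows
// (row index r = c + C*(i + kh*j) for kernel tap (i, j)) and P = Ho*Wo
// columns (column index p = ho + Ho*wo).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& C, int& H, int& W, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { C = d[0]; H = d[1]; W = d[2]; N = 1; }
  else if (d.size() == 4) { C = d[0]; H = d[1]; W = d[2]; N = d[3]; }
  else stop("feature map must have dim (C,H,W) or (C,H,W,N)");
}

static void im2col(const double* x, int C, int H, int W,
                   int kh, int kw, int stride, int pad, int dil,
                   arma::mat& col, int Ho, int Wo) {
  // col is K x P, pre-allocated
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      for (int j = 0; j < kw; ++j) {
        int wi = wo * stride - pad + j * dil;
        for (int i = 0; i < kh; ++i) {
          int hi = ho * stride - pad + i * dil;
          double* dst = col.colptr(p) + C * (i + kh * j);
          if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
            const double* src = x + C * (hi + H * wi);
            std::copy(src, src + C, dst);
          } else {
            std::fill(dst, dst + C, 0.0);
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int C, int H, int W,
                   int kh, int kw, int stride, int pad, int dil,
                   double* x, int Ho, int Wo) {
  // accumulates into x (must be zeroed by caller)
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      for (int j = 0; j < kw; ++j) {
        int wi = wo * stride - pad + j * dil;
        if (wi < 0 || wi >= W) continue;
        for (int i = 0; i < kh; ++i) {
          int hi = ho * stride - pad + i * dil;
          if (hi < 0 || hi >= H) continue;
          const double* src = col.colptr(p) + C * (i + kh * j);
          double* dst = x + C * (hi + H * wi);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim"); // (Cout, Cin, kh, kw)
  int Cout = wd[0], Cin = wd[1], kh = wd[2], kw = wd[3];
  if (Cin != C) stop("conv2d: input channels (%d) != weight Cin (%d)", C, Cin);
  int eff_h = (kh - 1) * dil + 1, eff_w = (kw - 1) * dil + 1;
  int Ho = (H + 2 * pad - eff_h) / stride + 1;
  int Wo = (W + 2 * pad - eff_w) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  int K = C * kh * kw, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false, true);
  arma::colvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y(static_cast<R_xlen_t>(Cout) * P * N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * C * H * W,
           C, H, W, kh, kw, stride, pad, dil, col, Ho, Wo);
    arma::mat yn(y.begin() + static_cast<R_xlen_t>(n) * Cout * P, Cout, P, false, true);
    yn = Wm * col;
    yn.each_col() += bv;
  }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, int dil) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[0], kh = wd[2], kw = wd[3];
  int Co2, Ho, Wo, N2; get_dims4(dy, Co2, Ho, Wo, N2);
  if (Co2 != Cout || N2 != N) stop("conv2d_bwd: inconsistent gradient shape");
  int K = C * kh * kw, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false, true);
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), Cout, K, false, true);
  arma::colvec dbv(db.begin(), Cout, false, true);

  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    im2col(xn, C, H, W, kh, kw, stride, pad, dil, col, Ho, Wo);
    arma::mat dyn(const_cast<double*>(dy.begin()) + static_cast<R_xlen_t>(n) * Cout * P,
                  Cout, P, false, true);
    dWm += dyn * col.t();
    dbv += arma::sum(dyn, 1);
    arma::mat dcol = Wm.t() * dyn; // K x P
    col2im(dcol, C, H, W, kh, kw, stride, pad, dil,
           dx.begin() + static_cast<R_xlen_t>(n) * C * H * W, Ho, Wo);
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(C) * Ho * Wo * N);
  IntegerVector idx(y.size()); // linear index into x slab of sample n, 0-based
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    double* yn = y.begin() + static_cast<R_xlen_t>(n) * C * Ho * Wo;
    int* in = idx.begin() + static_cast<R_xlen_t>(n) * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int best_ix = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              int ix = c + C * (hi + H * wi);
              if (xn[ix] > best) { best = xn[ix]; best_ix = ix; }
            }
          }
          // window fully in padding: treat as zero
          if (best_ix < 0) { best = 0.0; }
          yn[c + C * (ho + Ho * wo)] = best;
          in[c + C * (ho + Ho * wo)] = best_ix;
        }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  idx.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector idx,
                          int C, int H, int W) {
  int Co, Ho, Wo, N; get_dims4(dy, Co, Ho, Wo, N);
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  R_xlen_t per_out = static_cast<R_xlen_t>(Co) * Ho * Wo;
  R_xlen_t per_in = static_cast<R_xlen_t>(C) * H * W;
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + n * per_out;
    const int* in = idx.begin() + n * per_out;
    double* dxn = dx.begin() + n * per_in;
    for (R_xlen_t q = 0; q < per_out; ++q)
      if (in[q] >= 0) dxn[in[q]] += dyn[q];
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// Bilinear resize with half-pixel centers (align_corners = FALSE).
static inline void bilin_coeff(int out, int in, int o, int& i0, int& i1, double& a) {
  double s = (double)in / out;
  double pos = (o + 0.5) * s - 0.5;
  if (pos < 0) pos = 0;
  if (pos > in - 1) pos = in - 1;
  i0 = (int)std::floor(pos);
  i1 = std::min(i0 + 1, in - 1);
  a = pos - i0; // weight on i1
}

// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  NumericVector y(static_cast<R_xlen_t>(C) * Ho * Wo * N);
  std::vector<int> h0(Ho), h1(Ho); std::vector<double> ah(Ho);
  std::vector<int> w0(Wo), w1(Wo); std::vector<double> aw(Wo);
  for (int ho = 0; ho < Ho; ++ho) bilin_coeff(Ho, H, ho, h0[ho], h1[ho], ah[ho]);
  for (int wo = 0; wo < Wo; ++wo) bilin_coeff(Wo, W, wo, w0[wo], w1[wo], aw[wo]);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    double* yn = y.begin() + static_cast<R_xlen_t>(n) * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *p00 = xn + C * (h0[ho] + H * w0[wo]);
        const double *p10 = xn + C * (h1[ho] + H * w0[wo]);
        const double *p01 = xn + C * (h0[ho] + H * w1[wo]);
        const double *p11 = xn + C * (h1[ho] + H * w1[wo]);
        double b0 = 1.0 - ah[ho], b1 = ah[ho], c0 = 1.0 - aw[wo], c1 = aw[wo];
        double* q = yn + C * (ho + Ho * wo);
        for (int c = 0; c < C; ++c)
          q[c] = c0 * (b0 * p00[c] + b1 * p10[c]) + c1 * (b0 * p01[c] + b1 * p11[c]);
      }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd(NumericVector dy, int H, int W) {
  int C, Ho, Wo, N; get_dims4(dy, C, Ho, Wo, N);
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  std::vector<int> h0(Ho), h1(Ho); std::vector<double> ah(Ho);
  std::vector<int> w0(Wo), w1(Wo); std::vector<double> aw(Wo);
  for (int ho = 0; ho < Ho; ++ho) bilin_coeff(Ho, H, ho, h0[ho], h1[ho], ah[ho]);
  for (int wo = 0; wo < Wo; ++wo) bilin_coeff(Wo, W, wo, w0[wo], w1[wo], aw[wo]);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + static_cast<R_xlen_t>(n) * C * Ho * Wo;
    double* dxn = dx.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double b0 = 1.0 - ah[ho], b1 = ah[ho], c0 = 1.0 - aw[wo], c1 = aw[wo];
        const double* q = dyn + C * (ho + Ho * wo);
        double *p00 = dxn + C * (h0[ho] + H * w0[wo]);
        double *p10 = dxn + C * (h1[ho] + H * w0[wo]);
        double *p01 = dxn + C * (h0[ho] + H * w1[wo]);
        double *p11 = dxn + C * (h1[ho] + H * w1[wo]);
        for (int c = 0; c < C; ++c) {
          p00[c] += c0 * b0 * q[c];
          p10[c] += c0 * b1 * q[c];
          p01[c] += c1 * b0 * q[c];
          p11[c] += c1 * b1 * q[c];
        }
      }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}
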