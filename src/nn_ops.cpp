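// Minimal conv-net kernels used by the R training engine.
// Array layout is R column-major throughout:
//   activations x : dim (H, W, C, N)
//   weights    w : dim (kh, kw, Cin, Cout)
// im2col patch rows are ordered (kh, kw, Cin), matching the column-major
// flattening of w, so convolution reduces to one GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& a, int d[4]) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& P) {
  // P is (kh*kw*C) x (Ho*Wo), pre-allocated
  P.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wcol = wo * stride - pad + j;
          if (wcol < 0 || wcol >= W) continue;
          const double* xcol = xc + (size_t)wcol * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + i;
            if (h < 0 || h >= H) continue;
            P(r, ho + (size_t)Ho * wo) = xcol[h];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& P, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wcol = wo * stride - pad + j;
          if (wcol < 0 || wcol >= W) continue;
          double* xcol = xc + (size_t)wcol * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + i;
            if (h < 0 || h >= H) continue;
            xcol[h] += P(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("channel mismatch between input and weights");
  if (b.size() != Co) stop("bias length must equal the output channel count");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y(Ho * (size_t)Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);

  const int K = kh * kw * Ci;
  arma::mat P(K, (size_t)Ho * Wo);
  const arma::mat Wmat(const_cast<double*>(&w[0]), K, Co, false, true);
  const arma::rowvec bv(const_cast<double*>(&b[0]), Co, false, true);

  for (int n = 0; n < N; ++n) {
    const double* xn = &x[0] + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    arma::mat Y = P.t() * Wmat;       // (Ho*Wo) x Co
    Y.each_row() += bv;
    std::memcpy(&y[0] + (size_t)n * Ho * Wo * Co, Y.memptr(),
                sizeof(double) * Ho * Wo * Co);
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  int xd[4], wd[4], yd[4];
  get_dims4(x, xd); get_dims4(w, wd); get_dims4(dy, yd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Co || yd[3] != N) stop("gradient dimensions do not match");

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Co);

  const int K = kh * kw * Ci;
  arma::mat P(K, (size_t)Ho * Wo);
  const arma::mat Wmat(const_cast<double*>(&w[0]), K, Co, false, true);
  arma::mat dWacc(&dw[0], K, Co, false, true);
  arma::vec dbacc(&db[0], Co, false, true);

  for (int n = 0; n < N; ++n) {
    const double* xn = &x[0] + (size_t)n * H * W * C;
    const arma::mat dYmat(const_cast<double*>(&dy[0]) + (size_t)n * Ho * Wo * Co,
                          (size_t)Ho * Wo, Co, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    dWacc += P * dYmat;
    dbacc += arma::sum(dYmat, 0).t();
    arma::mat dP = Wmat * dYmat.t();   // K x (Ho*Wo)
    col2im_add(dP, H, W, C, kh, kw, stride, pad, Ho, Wo,
               &dx[0] + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int k, int stride) {
  int xd[4];
  get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H - k) / stride + 1;
  int Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("pooling window larger than input");

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based index into the (H, W) plane
  idx.attr("dim") = y.attr("dim");

  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = &x[0] + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = 0;
          for (int j = 0; j < k; ++j) {
            int wc = wo * stride + j;
            for (int i = 0; i < k; ++i) {
              int h = ho * stride + i;
              double v = plane[h + (size_t)wc * H];
              if (v > best) { best = v; besti = h + wc * H; }
            }
          }
          // column-major output order is (ho, wo, c, n); emit accordingly
          size_t out = (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * c +
                       (size_t)Ho * Wo * C * n;
          y[out] = best;
          idx[out] = besti;
          (void)q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector dy, IntegerVector idx,
                             IntegerVector xdim) {
  if (xdim.size() != 4) stop("xdim must have length 4");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int yd[4];
  {
    IntegerVector dim = dy.attr("dim");
    for (int i = 0; i < 4; ++i) yd[i] = dim[i];
  }
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = &dx[0] + ((size_t)n * C + c) * H * W;
      const size_t base = (size_t)Ho * Wo * c + (size_t)Ho * Wo * C * n;
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) {
        plane[idx[base + q]] += dy[base + q];
      }
    }
  }
  return dx;
}
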