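// Convolution / pooling kernels for the small conv-net engine.
// Array layout follows R column-major conventions:
//   activations  x : H x W x C x N
//   conv weights w : kh x kw x C x OC   (depthwise: kh x kw x C)
// Convolutions use zero padding `pad` on all sides and square stride.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static IntegerVector dims_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return d;
}

// Build im2col patch matrix for one sample: (kh*kw*C) x (OH*OW)
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int s, int p, int OH, int OW,
                   arma::mat& P) {
  const double* xs = x + (size_t)H * W * C * n;
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      int h0 = oh * s - p, w0 = ow * s - p;
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            int h = h0 + i, w = w0 + j;
            double v = (h >= 0 && h < H && w >= 0 && w < W)
              ? xs[h + (size_t)H * (w + (size_t)W * c)] : 0.0;
            P(i + kh * (j + kw * c), col) = v;
          }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  int OH = out_size(H, kh, stride, pad), OW = out_size(W, kw, stride, pad);
  if (OH < 1 || OW < 1) stop("convolution output would be empty");
  arma::mat Wm(OC, kh * kw * C);
  for (int oc = 0; oc < OC; ++oc)
    for (int r = 0; r < kh * kw * C; ++r)
      Wm(oc, r) = w[r + (size_t)kh * kw * C * oc];
  NumericVector y((size_t)OH * OW * OC * N);
  y.attr("dim") = IntegerVector::create(OH, OW, OC, N);
  arma::mat P(kh * kw * C, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x), H, W, C, n, kh, kw, stride, pad, OH, OW, P);
    arma::mat Y = Wm * P;  // OC x (OH*OW)
    double* yn = REAL(y) + (size_t)OH * OW * OC * n;
    for (int oc = 0; oc < OC; ++oc)
      for (int col = 0; col < OH * OW; ++col)
        yn[col % OH + (size_t)OH * (col / OH + (size_t)OW * oc)] =
          Y(oc, col) + b[oc];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector gy,
                 int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), gd = dims_of(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  int OH = gd[0], OW = gd[1];
  arma::mat Wm(OC, kh * kw * C);
  for (int oc = 0; oc < OC; ++oc)
    for (int r = 0; r < kh * kw * C; ++r)
      Wm(oc, r) = w[r + (size_t)kh * kw * C * oc];
  arma::mat dWm(OC, kh * kw * C, arma::fill::zeros);
  arma::vec db(OC, arma::fill::zeros);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat P(kh * kw * C, OH * OW), G(OC, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x), H, W, C, n, kh, kw, stride, pad, OH, OW, P);
    const double* gn = REAL(gy) + (size_t)OH * OW * OC * n;
    for (int oc = 0; oc < OC; ++oc)
      for (int col = 0; col < OH * OW; ++col)
        G(oc, col) = gn[col % OH + (size_t)OH * (col / OH + (size_t)OW * oc)];
    dWm += G * P.t();
    db += arma::sum(G, 1);
    arma::mat dP = Wm.t() * G;  // (kh*kw*C) x (OH*OW)
    double* dxn = REAL(dx) + (size_t)H * W * C * n;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        int col = oh + OH * ow;
        int h0 = oh * stride - pad, w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i) {
              int h = h0 + i, wcol = w0 + j;
              if (h >= 0 && h < H && wcol >= 0 && wcol < W)
                dxn[h + (size_t)H * (wcol + (size_t)W * c)] +=
                  dP(i + kh * (j + kw * c), col);
            }
      }
  }
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int oc = 0; oc < OC; ++oc)
    for (int r = 0; r < kh * kw * C; ++r)
      dw[r + (size_t)kh * kw * C * oc] = dWm(oc, r);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int OH = out_size(H, kh, stride, pad), OW = out_size(W, kw, stride, pad);
  if (OH < 1 || OW < 1) stop("depthwise output would be empty");
  NumericVector y((size_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = REAL(x) + (size_t)H * W * C * n;
    double* yn = REAL(y) + (size_t)OH * OW * C * n;
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double acc = b[c];
          int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i) {
              int h = h0 + i, wc = w0 + j;
              if (h >= 0 && h < H && wc >= 0 && wc < W)
                acc += w[i + kh * (j + kw * c)] *
                  xn[h + (size_t)H * (wc + (size_t)W * c)];
            }
          yn[oh + (size_t)OH * (ow + (size_t)OW * c)] = acc;
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), gd = dims_of(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int OH = gd[0], OW = gd[1];
  NumericVector dx(x.size()), dw(w.size()), db(C);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    const double* xn = REAL(x) + (size_t)H * W * C * n;
    const double* gn = REAL(gy) + (size_t)OH * OW * C * n;
    double* dxn = REAL(dx) + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double g = gn[oh + (size_t)OH * (ow + (size_t)OW * c)];
          db[c] += g;
          int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i) {
              int h = h0 + i, wc = w0 + j;
              if (h >= 0 && h < H && wc >= 0 && wc < W) {
                dw[i + kh * (j + kw * c)] +=
                  g * xn[h + (size_t)H * (wc + (size_t)W * c)];
                dxn[h + (size_t)H * (wc + (size_t)W * c)] +=
                  g * w[i + kh * (j + kw * c)];
              }
            }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = out_size(H, k, stride, 0), OW = out_size(W, k, stride, 0);
  if (OH < 1 || OW < 1) stop("pooling output would be empty");
  NumericVector y((size_t)OH * OW * C * N);
  IntegerVector idx((size_t)OH * OW * C * N);  // argmax within H*W plane
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  idx.attr("dim") = IntegerVector::create(OH, OW, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = REAL(x) + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -INFINITY;
          int besti = 0;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i) {
              int h = oh * stride + i, wc = ow * stride + j;
              if (h < H && wc < W) {
                double v = xn[h + (size_t)H * (wc + (size_t)W * c)];
                if (v > best) { best = v; besti = h + H * wc; }
              }
            }
          size_t o = oh + (size_t)OH * (ow + (size_t)OW * (c + (size_t)C * n));
          y[o] = best;
          idx[o] = besti;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector xdim, IntegerVector idx,
                             NumericVector gy) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector gd = dims_of(gy);
  int OH = gd[0], OW = gd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          size_t o = oh + (size_t)OH * (ow + (size_t)OW * (c + (size_t)C * n));
          dx[idx[o] + (size_t)H * W * (c + (size_t)C * n)] += gy[o];
        }
  return dx;
}

// In-place Adam update; p, m, v are owned by the training loop.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, int t, double b1,
                     double b2, double eps) {
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
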