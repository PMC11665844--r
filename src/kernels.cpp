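// Low-level tensor kernels for the network core.
// Tensor layout everywhere: column-major R array dim = c(C, H, W, N)
// (channel fastest), so a sample's (O x Ho*Wo) GEMM result can be copied
// straight into the output buffer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& C, int& H, int& W, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (C,H,W,N), got %d dims", (int)d.size());
  C = d[0]; H = d[1]; W = d[2]; N = d[3];
}

// im2col for one sample: col is K x P, K = C*kh*kw (k = c + C*(ki + kh*kj)),
// P = Ho*Wo (p = ho + Ho*wo). Out-of-range taps contribute zero.
static void im2col(const double* xs, int C, int H, int W,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      for (int kj = 0; kj < kw; ++kj) {
        const int w = wo * stride - pad + kj * dil;
        if (w < 0 || w >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int h = ho * stride - pad + ki * dil;
          if (h < 0 || h >= H) continue;
          const double* src = xs + (size_t)C * (h + (size_t)H * w);
          double* dst = col.colptr(p) + (size_t)C * (ki + (size_t)kh * kj);
          std::copy(src, src + C, dst);
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int C, int H, int W,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, double* xs) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      for (int kj = 0; kj < kw; ++kj) {
        const int w = wo * stride - pad + kj * dil;
        if (w < 0 || w >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int h = ho * stride - pad + ki * dil;
          if (h < 0 || h >= H) continue;
          const double* src = col.colptr(p) + (size_t)C * (ki + (size_t)kh * kj);
          double* dst = xs + (size_t)C * (h + (size_t)H * w);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                             int stride, int pad, int dil) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim"); // (C_in, kh, kw, C_out)
  if (wd.size() != 4) stop("weight must be 4-d (C_in, kh, kw, C_out)");
  const int Ci = wd[0], kh = wd[1], kw = wd[2], O = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels but weight expects %d", C, Ci);
  const int Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  const int Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = C * kh * kw, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, O, false, true);
  NumericVector y(O * (R_xlen_t)P * N);
  y.attr("dim") = IntegerVector::create(O, Ho, Wo, N);
  arma::mat col(K, P);
  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = arma::vec(NumericVector(bias).begin(), O);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * C * H * W;
    im2col(xs, C, H, W, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat ys(y.begin() + (size_t)n * O * P, O, P, false, true);
    ys = Wm.t() * col;
    if (has_b) ys.each_col() += b;
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil, bool need_dx) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[1], kw = wd[2], O = wd[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[1], Wo = yd[2];
  const int K = C * kh * kw, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, O, false, true);
  NumericVector dwv(w.size()); dwv.attr("dim") = wd;
  arma::mat dW(dwv.begin(), K, O, false, true);
  NumericVector db(O);
  arma::vec dbv(db.begin(), O, false, true);
  NumericVector dx;
  if (need_dx) { dx = NumericVector(x.size()); dx.attr("dim") = x.attr("dim"); }

  arma::mat col(K, P), dcol(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * C * H * W;
    arma::mat dys(dy.begin() + (size_t)n * O * P, O, P, false, true);
    im2col(xs, C, H, W, kh, kw, stride, pad, dil, Ho, Wo, col);
    dW += col * dys.t();
    dbv += arma::sum(dys, 1);
    if (need_dx) {
      dcol = Wm * dys;
      col2im(dcol, C, H, W, kh, kw, stride, pad, dil, Ho, Wo,
             dx.begin() + (size_t)n * C * H * W);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// 2x2 stride-2 max-pool; ties broken by first scanned index (h then w).
// [[Rcpp::export(rng = false)]]
List maxpool2_fwd_cpp(NumericVector x) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  if (H % 2 || W % 2) stop("maxpool2: spatial size (%d x %d) must be even", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  IntegerVector idx(y.size()); // 0-based flat index into x of the argmax
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + c + (size_t)C * ((2 * ho + dh) + (size_t)H * (2 * wo + dw));
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          // y layout (c, ho, wo, n): channel fastest, but we iterate c innermost
          const R_xlen_t yi = c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
          y[yi] = best; idx[yi] = (int)bi; (void)q;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Channel-wise max map with argmax channel (for spatial attention).
// [[Rcpp::export(rng = false)]]
List channel_max_fwd_cpp(NumericVector x) {
  int C, H, W, N; get_dims4(x, C, H, W, N);
  R_xlen_t P = (R_xlen_t)H * W * N;
  NumericVector y(P);
  y.attr("dim") = IntegerVector::create(1, H, W, N);
  IntegerVector arg(P);
  for (R_xlen_t p = 0; p < P; ++p) {
    const double* col = x.begin() + (size_t)p * C;
    int bi = 0; double best = col[0];
    for (int c = 1; c < C; ++c) if (col[c] > best) { best = col[c]; bi = c; }
    y[p] = best; arg[p] = bi;
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector channel_max_bwd_cpp(NumericVector dy, IntegerVector arg, IntegerVector xdim) {
  const int C = xdim[0];
  R_xlen_t n = (R_xlen_t)C * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[(size_t)p * C + arg[p]] += dy[p];
  return dx;
}
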