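// Convolution kernels for the backbone. Feature batches use the layout
// (H, W, N, C) in column-major order, matching R arrays with
// dim = c(H, W, N, C); weights are (k, k, Cin, Cout) for dense convolutions
// and (k, k, C) for depthwise ones. Dense convolutions go through an
// im2col + GEMM path (Armadillo), depthwise ones through direct loops.
// Padding is symmetric, stride >= 1, no dilation, no bias (batch norm
// follows every convolution).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int i, int j, int n, int c,
                            int H, int W, int N) {
  return i + (R_xlen_t)H * (j + (R_xlen_t)W * (n + (R_xlen_t)N * c));
}

// Gather the im2col matrix A (Ho*Wo x k*k*Cin) for image n.
static void im2col(const double* x, int H, int W, int N, int Cin, int n,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& A) {
  A.zeros();
  for (int ci = 0; ci < Cin; ci++) {
    for (int kj = 0; kj < k; kj++) {
      for (int ki = 0; ki < k; ki++) {
        int col = ki + k * (kj + k * ci);
        double* acol = A.colptr(col);
        for (int oj = 0; oj < Wo; oj++) {
          int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; oi++) {
            int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            acol[oi + Ho * oj] = x[idx4(i, j, n, ci, H, W, N)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight Cin (%d) != input C (%d)", wd[2], Cin);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * N * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);
  arma::mat Wm(w.begin(), (R_xlen_t)k * k * Cin, Cout, false, true);
  arma::mat A(Ho * Wo, k * k * Cin);
  for (int n = 0; n < N; n++) {
    im2col(x.begin(), H, W, N, Cin, n, k, stride, pad, Ho, Wo, A);
    arma::mat Yn = A * Wm;  // (Ho*Wo, Cout)
    for (int co = 0; co < Cout; co++) {
      std::copy(Yn.colptr(co), Yn.colptr(co) + (R_xlen_t)Ho * Wo,
                y.begin() + (R_xlen_t)Ho * Wo * (n + (R_xlen_t)N * co));
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * N * Cin);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)k * k * Cin * Cout);
  dw.attr("dim") = wd;
  arma::mat Wm(w.begin(), (R_xlen_t)k * k * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), (R_xlen_t)k * k * Cin, Cout, false, true);
  arma::mat A(Ho * Wo, k * k * Cin);
  arma::mat dYn(Ho * Wo, Cout);
  for (int n = 0; n < N; n++) {
    for (int co = 0; co < Cout; co++) {
      std::copy(dy.begin() + (R_xlen_t)Ho * Wo * (n + (R_xlen_t)N * co),
                dy.begin() + (R_xlen_t)Ho * Wo * (n + (R_xlen_t)N * co) + (R_xlen_t)Ho * Wo,
                dYn.colptr(co));
    }
    im2col(x.begin(), H, W, N, Cin, n, k, stride, pad, Ho, Wo, A);
    dWm += A.t() * dYn;
    arma::mat dA = dYn * Wm.t();  // (Ho*Wo, k*k*Cin)
    // col2im scatter-add
    for (int ci = 0; ci < Cin; ci++) {
      for (int kj = 0; kj < k; kj++) {
        for (int ki = 0; ki < k; ki++) {
          int col = ki + k * (kj + k * ci);
          const double* dcol = dA.colptr(col);
          for (int oj = 0; oj < Wo; oj++) {
            int j = oj * stride + kj - pad;
            if (j < 0 || j >= W) continue;
            for (int oi = 0; oi < Ho; oi++) {
              int i = oi * stride + ki - pad;
              if (i < 0 || i >= H) continue;
              dx[idx4(i, j, n, ci, H, W, N)] += dcol[oi + Ho * oj];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  int k = wd[0];
  if (wd[2] != C) stop("dwconv2d: weight C (%d) != input C (%d)", wd[2], C);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * N * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  for (int c = 0; c < C; c++) {
    const double* wc = w.begin() + (R_xlen_t)k * k * c;
    for (int n = 0; n < N; n++) {
      const double* xs = x.begin() + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      double* ys = y.begin() + (R_xlen_t)Ho * Wo * (n + (R_xlen_t)N * c);
      for (int oj = 0; oj < Wo; oj++) {
        for (int oi = 0; oi < Ho; oi++) {
          double acc = 0.0;
          for (int kj = 0; kj < k; kj++) {
            int j = oj * stride + kj - pad;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ki++) {
              int i = oi * stride + ki - pad;
              if (i < 0 || i >= H) continue;
              acc += xs[i + (R_xlen_t)H * j] * wc[ki + k * kj];
            }
          }
          ys[oi + Ho * oj] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  int k = wd[0];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * N * C);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)k * k * C);
  dw.attr("dim") = wd;
  for (int c = 0; c < C; c++) {
    const double* wc = w.begin() + (R_xlen_t)k * k * c;
    double* dwc = dw.begin() + (R_xlen_t)k * k * c;
    for (int n = 0; n < N; n++) {
      const double* xs = x.begin() + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      double* dxs = dx.begin() + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      const double* dys = dy.begin() + (R_xlen_t)Ho * Wo * (n + (R_xlen_t)N * c);
      for (int oj = 0; oj < Wo; oj++) {
        for (int oi = 0; oi < Ho; oi++) {
          double g = dys[oi + Ho * oj];
          if (g == 0.0) continue;
          for (int kj = 0; kj < k; kj++) {
            int j = oj * stride + kj - pad;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ki++) {
              int i = oi * stride + ki - pad;
              if (i < 0 || i >= H) continue;
              dxs[i + (R_xlen_t)H * j] += g * wc[ki + k * kj];
              dwc[ki + k * kj] += g * xs[i + (R_xlen_t)H * j];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
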