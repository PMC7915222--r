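// Elementwise / per-channel kernels for the hot training path. A feature
// batch (H, W, N, C) is treated as C contiguous slabs of H*W*N values for
// batch norm, and as N*C contiguous blocks of H*W values for the channel
// scaling used by squeeze-and-excitation and pooling gradients.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Per-channel mean and (biased) variance over slabs of size n.
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, int C) {
  R_xlen_t n = x.size() / C;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; c++) {
    const double* p = x.begin() + n * c;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; i++) { s += p[i]; s2 += p[i] * p[i]; }
    mu[c] = s / n;
    var[c] = s2 / n - mu[c] * mu[c];
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// y = xhat * gamma + beta with xhat = (x - mu) * inv; returns both.
// [[Rcpp::export]]
List bn_apply_cpp(NumericVector x, NumericVector mu, NumericVector inv,
                  NumericVector gamma, NumericVector beta) {
  int C = mu.size();
  R_xlen_t n = x.size() / C;
  NumericVector y(x.size()), xhat(x.size());
  for (int c = 0; c < C; c++) {
    const double* p = x.begin() + n * c;
    double* ph = xhat.begin() + n * c;
    double* py = y.begin() + n * c;
    double m = mu[c], iv = inv[c], g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < n; i++) {
      ph[i] = (p[i] - m) * iv;
      py[i] = ph[i] * g + b;
    }
  }
  if (x.hasAttribute("dim")) {
    y.attr("dim") = x.attr("dim");
    xhat.attr("dim") = x.attr("dim");
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Training-mode batch-norm backward:
// dx = gamma*inv * (dy - mean(dy) - xhat * mean(dy*xhat)) per channel.
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector gi,
                bool training) {
  int C = gi.size();
  R_xlen_t n = dy.size() / C;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; c++) {
    const double* pd = dy.begin() + n * c;
    const double* ph = xhat.begin() + n * c;
    double* px = dx.begin() + n * c;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; i++) { sg += pd[i] * ph[i]; sb += pd[i]; }
    dgamma[c] = sg;
    dbeta[c] = sb;
    double g = gi[c];
    if (training) {
      double mg = sg / n, mb = sb / n;
      for (R_xlen_t i = 0; i < n; i++)
        px[i] = g * (pd[i] - mb - ph[i] * mg);
    } else {
      for (R_xlen_t i = 0; i < n; i++) px[i] = g * pd[i];
    }
  }
  if (dy.hasAttribute("dim")) dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List swish_fwd_cpp(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) {
    s[i] = sigmoid(x[i]);
    y[i] = x[i] * s[i];
  }
  if (x.hasAttribute("dim")) {
    y.attr("dim") = x.attr("dim");
    s.attr("dim") = x.attr("dim");
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector swish_bwd_cpp(NumericVector x, NumericVector s,
                            NumericVector dy) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) {
    dx[i] = dy[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  }
  if (x.hasAttribute("dim")) dx.attr("dim") = x.attr("dim");
  return dx;
}

// Multiply block b (size hw) of x by s[b].
// [[Rcpp::export]]
NumericVector chan_scale_cpp(NumericVector x, NumericVector s, int hw) {
  NumericVector y(x.size());
  R_xlen_t nb = s.size();
  for (R_xlen_t b = 0; b < nb; b++) {
    const double* p = x.begin() + (R_xlen_t)hw * b;
    double* py = y.begin() + (R_xlen_t)hw * b;
    double v = s[b];
    for (int i = 0; i < hw; i++) py[i] = p[i] * v;
  }
  if (x.hasAttribute("dim")) y.attr("dim") = x.attr("dim");
  return y;
}

// Per-block dot product sum(x*dy) over blocks of size hw.
// [[Rcpp::export]]
NumericVector chan_dot_cpp(NumericVector x, NumericVector dy, int hw) {
  R_xlen_t nb = x.size() / hw;
  NumericVector out(nb);
  for (R_xlen_t b = 0; b < nb; b++) {
    const double* p = x.begin() + (R_xlen_t)hw * b;
    const double* pd = dy.begin() + (R_xlen_t)hw * b;
    double s = 0;
    for (int i = 0; i < hw; i++) s += p[i] * pd[i];
    out[b] = s;
  }
  return out;
}

// Expand v[b] into blocks of size hw, scaled by 1/hw (pooling gradient).
// [[Rcpp::export]]
NumericVector chan_expand_cpp(NumericVector v, int hw) {
  NumericVector out((R_xlen_t)v.size() * hw);
  for (R_xlen_t b = 0; b < v.size(); b++) {
    double val = v[b] / hw;
    double* p = out.begin() + (R_xlen_t)hw * b;
    for (int i = 0; i < hw; i++) p[i] = val;
  }
  return out;
}

// Per-block means of blocks of size hw (global average pooling).
// [[Rcpp::export]]
NumericVector block_means_cpp(NumericVector x, int hw) {
  R_xlen_t nb = x.size() / hw;
  NumericVector out(nb);
  for (R_xlen_t b = 0; b < nb; b++) {
    const double* p = x.begin() + (R_xlen_t)hw * b;
    double s = 0;
    for (int i = 0; i < hw; i++) s += p[i];
    out[b] = s / hw;
  }
  return out;
}
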