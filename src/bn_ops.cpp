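// Fused per-channel batch-norm kernels for (L, C, B) arrays: single-pass
// moments, normalization, affine, and the backward reductions. These touch
// the largest arrays in the network (the first-stage output), where R-level
// reshapes would copy tens of MB per call.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_channel_moments")]]
NumericMatrix cpp_channel_moments(NumericVector x, IntegerVector d) {
  const int L = d[0], C = d[1], B = d[2];
  NumericMatrix out(2, C);
  const double* xp = x.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* col = xp + (static_cast<size_t>(b) * C + c) * L;
      double s = 0.0, ss = 0.0;
      for (int t = 0; t < L; ++t) { s += col[t]; ss += col[t] * col[t]; }
      out(0, c) += s;
      out(1, c) += ss;
    }
  return out;
}

// One pass producing both xhat = (x - mu_c) * inv_sd_c and
// y = xhat * gamma_c + beta_c.
// [[Rcpp::export(name = ".cpp_bn_norm_affine")]]
List cpp_bn_norm_affine(NumericVector x, IntegerVector d,
                        NumericVector mu, NumericVector inv_sd,
                        NumericVector gamma, NumericVector beta) {
  const int L = d[0], C = d[1], B = d[2];
  NumericVector xhat(x.size()), y(x.size());
  const double* xp = x.begin();
  double* hp = xhat.begin();
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = (static_cast<size_t>(b) * C + c) * L;
      const double m = mu[c], s = inv_sd[c], g = gamma[c], a = beta[c];
      for (int t = 0; t < L; ++t) {
        const double h = (xp[off + t] - m) * s;
        hp[off + t] = h;
        yp[off + t] = h * g + a;
      }
    }
  xhat.attr("dim") = d;
  y.attr("dim") = d;
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// y = x * mul_c + off_c
// [[Rcpp::export(name = ".cpp_scale_shift")]]
NumericVector cpp_scale_shift(NumericVector x, IntegerVector d,
                              NumericVector mul, NumericVector off) {
  const int L = d[0], C = d[1], B = d[2];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = (static_cast<size_t>(b) * C + c) * L;
      const double m = mul[c], a = off[c];
      for (int t = 0; t < L; ++t) yp[o + t] = xp[o + t] * m + a;
    }
  y.attr("dim") = d;
  return y;
}

// rows: (sum dy*xhat, sum dy) per channel
// [[Rcpp::export(name = ".cpp_bn_bwd_sums")]]
NumericMatrix cpp_bn_bwd_sums(NumericVector dy, NumericVector xhat,
                              IntegerVector d) {
  const int L = d[0], C = d[1], B = d[2];
  NumericMatrix out(2, C);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = (static_cast<size_t>(b) * C + c) * L;
      double sg = 0.0, sb = 0.0;
      for (int t = 0; t < L; ++t) {
        sg += dp[o + t] * hp[o + t];
        sb += dp[o + t];
      }
      out(0, c) += sg;
      out(1, c) += sb;
    }
  return out;
}

// dx = (dy - mean_dy_c - xhat * mean_dyxhat_c) * scale_c
// [[Rcpp::export(name = ".cpp_bn_dx")]]
NumericVector cpp_bn_dx(NumericVector dy, NumericVector xhat, IntegerVector d,
                        NumericVector mean_dy, NumericVector mean_dyxhat,
                        NumericVector scale) {
  const int L = d[0], C = d[1], B = d[2];
  NumericVector dx(dy.size());
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  double* op = dx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t o = (static_cast<size_t>(b) * C + c) * L;
      const double m1 = mean_dy[c], m2 = mean_dyxhat[c], sc = scale[c];
      for (int t = 0; t < L; ++t)
        op[o + t] = (dp[o + t] - m1 - hp[o + t] * m2) * sc;
    }
  dx.attr("dim") = d;
  return dx;
}
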