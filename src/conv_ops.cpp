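// Grouped 1-D temporal convolutions and the spatial depthwise contraction.
// Feature maps are column-major R arrays laid out (time L, channel C, batch B)
// so each channel's time series is contiguous. Convolutions are
// cross-correlations with "same" zero padding (even kernels pad one extra
// sample on the left) and no bias, evaluated as im2col + GEMM with several
// batch items stacked per GEMM call.
//
// The templated kernels run in double (exact, the default for standalone
// use) or single precision (the network's training default, matching the
// conventions of deep-learning frameworks; halves the memory traffic of the
// dominant im2col + GEMM path).

#include <RcppArmadillo.h>
using namespace Rcpp;

// rows of Xc: (t within item, item within chunk); cols: (tau, c_local).
// Reads the double-precision R array and writes the working type directly,
// so no separate conversion pass is needed.
template <typename T>
static void im2col_chunk(const double* x, int L, int C, int b0, int nb,
                         int c0, int cpg, int K, int pad_left,
                         arma::Mat<T>& Xc) {
  for (int cl = 0; cl < cpg; ++cl) {
    for (int tau = 0; tau < K; ++tau) {
      T* dst0 = Xc.colptr(cl * K + tau);
      const int shift = tau - pad_left;
      const int t0 = std::max(0, -shift);
      const int t1 = std::min(L, L - shift);
      for (int i = 0; i < nb; ++i) {
        const double* xc =
            x + (static_cast<size_t>(b0 + i) * C + (c0 + cl)) * L;
        T* dst = dst0 + static_cast<size_t>(i) * L;
        for (int t = 0; t < t0; ++t) dst[t] = T(0);
        for (int t = t0; t < t1; ++t) dst[t] = static_cast<T>(xc[t + shift]);
        for (int t = t1; t < L; ++t) dst[t] = T(0);
      }
    }
  }
}

static int chunk_items(int L, int cols) {
  // keep the im2col buffer around 2 MB
  int nb = static_cast<int>(262144 / (static_cast<double>(L) * cols));
  return std::max(1, nb);
}

template <typename T>
static void conv1d_fwd_core(const double* xp, const T* wp, double* yp,
                            int L, int C, int B, int K, int Cpg, int Cout,
                            int groups) {
  const int Fpg = Cout / groups;
  const int pad_left = K / 2;
  const int cols = Cpg * K;
  const int nb_max = chunk_items(L, cols);
  arma::Mat<T> Xc(static_cast<size_t>(nb_max) * L, cols);
  for (int b0 = 0; b0 < B; b0 += nb_max) {
    const int nb = std::min(nb_max, B - b0);
    arma::Mat<T> Xv(Xc.memptr(), static_cast<size_t>(nb) * L, cols, false,
                    true);
    for (int g = 0; g < groups; ++g) {
      im2col_chunk(xp, L, C, b0, nb, g * Cpg, Cpg, K, pad_left, Xv);
      const arma::Mat<T> Wg(const_cast<T*>(wp) +
                                static_cast<size_t>(g) * Fpg * K * Cpg,
                            K * Cpg, Fpg, false, true);
      arma::Mat<T> Yg = Xv * Wg;       // (nb*L) x Fpg
      for (int i = 0; i < nb; ++i)
        for (int f = 0; f < Fpg; ++f) {
          const T* src = Yg.colptr(f) + static_cast<size_t>(i) * L;
          double* dst = yp + ((static_cast<size_t>(b0 + i) * Cout) +
                              g * Fpg + f) * L;
          for (int t = 0; t < L; ++t) dst[t] = src[t];
        }
    }
  }
}

template <typename T>
static void conv1d_bwd_core(const double* xp, const T* wp, const double* dyp,
                            double* dwp, double* dxp,
                            int L, int C, int B, int K, int Cpg, int Cout,
                            int groups, bool need_dx) {
  const int Fpg = Cout / groups;
  const int pad_left = K / 2;
  const int cols = Cpg * K;
  const int nb_max = chunk_items(L, cols);
  arma::Mat<T> Xc(static_cast<size_t>(nb_max) * L, cols);
  arma::Mat<T> dYc(static_cast<size_t>(nb_max) * L, Fpg);
  for (int b0 = 0; b0 < B; b0 += nb_max) {
    const int nb = std::min(nb_max, B - b0);
    arma::Mat<T> Xv(Xc.memptr(), static_cast<size_t>(nb) * L, cols, false,
                    true);
    arma::Mat<T> dYv(dYc.memptr(), static_cast<size_t>(nb) * L, Fpg, false,
                     true);
    for (int g = 0; g < groups; ++g) {
      im2col_chunk(xp, L, C, b0, nb, g * Cpg, Cpg, K, pad_left, Xv);
      for (int i = 0; i < nb; ++i)
        for (int f = 0; f < Fpg; ++f) {
          const double* src = dyp + ((static_cast<size_t>(b0 + i) * Cout) +
                                     g * Fpg + f) * L;
          T* dst = dYv.colptr(f) + static_cast<size_t>(i) * L;
          for (int t = 0; t < L; ++t) dst[t] = static_cast<T>(src[t]);
        }
      arma::Mat<T> dWg = Xv.t() * dYv;  // (Cpg*K) x Fpg
      double* dwg = dwp + static_cast<size_t>(g) * Fpg * K * Cpg;
      for (size_t j = 0; j < dWg.n_elem; ++j) dwg[j] += dWg[j];
      if (need_dx) {
        const arma::Mat<T> Wg(const_cast<T*>(wp) +
                                  static_cast<size_t>(g) * Fpg * K * Cpg,
                              K * Cpg, Fpg, false, true);
        arma::Mat<T> dXc = dYv * Wg.t();
        for (int cl = 0; cl < Cpg; ++cl)
          for (int tau = 0; tau < K; ++tau) {
            const T* src = dXc.colptr(cl * K + tau);
            const int shift = tau - pad_left;
            const int t0 = std::max(0, -shift);
            const int t1 = std::min(L, L - shift);
            for (int i = 0; i < nb; ++i) {
              double* dxc = dxp + ((static_cast<size_t>(b0 + i) * C) +
                                   g * Cpg + cl) * L;
              const T* s = src + static_cast<size_t>(i) * L;
              for (int t = t0; t < t1; ++t) dxc[t + shift] += s[t];
            }
          }
      }
    }
  }
}

template <typename T>
static std::vector<T> to_vec(const NumericVector& v) {
  std::vector<T> out(v.size());
  const double* p = v.begin();
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = static_cast<T>(p[i]);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv1d_fwd")]]
NumericVector cpp_conv1d_fwd(NumericVector x, NumericVector w,
                             IntegerVector xdim, IntegerVector wdim,
                             int groups, bool single) {
  const int L = xdim[0], C = xdim[1], B = xdim[2];
  const int K = wdim[0], Cpg = wdim[1], Cout = wdim[2];
  if (C != Cpg * groups) stop("channel/group mismatch in conv1d");
  NumericVector y(static_cast<R_xlen_t>(L) * Cout * B);
  if (single) {
    std::vector<float> wf = to_vec<float>(w);
    conv1d_fwd_core<float>(x.begin(), wf.data(), y.begin(),
                           L, C, B, K, Cpg, Cout, groups);
  } else {
    conv1d_fwd_core<double>(x.begin(), w.begin(), y.begin(),
                            L, C, B, K, Cpg, Cout, groups);
  }
  y.attr("dim") = IntegerVector::create(L, Cout, B);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv1d_bwd")]]
List cpp_conv1d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim, IntegerVector wdim,
                    int groups, bool need_dx, bool single) {
  const int L = xdim[0], C = xdim[1], B = xdim[2];
  const int K = wdim[0], Cpg = wdim[1], Cout = wdim[2];
  NumericVector dw(w.size());
  NumericVector dx(need_dx ? x.size() : 0);
  if (single) {
    std::vector<float> wf = to_vec<float>(w);
    conv1d_bwd_core<float>(x.begin(), wf.data(), dy.begin(), dw.begin(),
                           need_dx ? dx.begin() : nullptr,
                           L, C, B, K, Cpg, Cout, groups, need_dx);
  } else {
    conv1d_bwd_core<double>(x.begin(), w.begin(), dy.begin(), dw.begin(),
                            need_dx ? dx.begin() : nullptr,
                            L, C, B, K, Cpg, Cout, groups, need_dx);
  }
  if (need_dx) dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Spatial depthwise stage: contracts the electrode axis.
// x: (L, F, H, B); w: (H, D, F); y: (L, F*D, B), out channel (f*D + m).
// [[Rcpp::export(name = ".cpp_spatial_dw_fwd")]]
NumericVector cpp_spatial_dw_fwd(NumericVector x, NumericVector w,
                                 IntegerVector xdim, IntegerVector wdim) {
  const int L = xdim[0], F = xdim[1], H = xdim[2], B = xdim[3];
  const int D = wdim[1];
  NumericVector y(static_cast<R_xlen_t>(L) * F * D * B);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int m = 0; m < D; ++m) {
        double* yc = yp + (static_cast<size_t>(b) * F * D + f * D + m) * L;
        for (int h = 0; h < H; ++h) {
          const double wv = wp[(static_cast<size_t>(f) * D + m) * H + h];
          const double* xc =
              xp + ((static_cast<size_t>(b) * H + h) * F + f) * L;
          for (int t = 0; t < L; ++t) yc[t] += wv * xc[t];
        }
      }
  y.attr("dim") = IntegerVector::create(L, F * D, B);
  return y;
}

// [[Rcpp::export(name = ".cpp_spatial_dw_bwd")]]
List cpp_spatial_dw_bwd(NumericVector x, NumericVector w, NumericVector dy,
                        IntegerVector xdim, IntegerVector wdim,
                        bool need_dx) {
  const int L = xdim[0], F = xdim[1], H = xdim[2], B = xdim[3];
  const int D = wdim[1];
  NumericVector dw(w.size());
  NumericVector dx(need_dx ? x.size() : 0);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dwp = dw.begin();
  double* dxp = need_dx ? dx.begin() : nullptr;
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int m = 0; m < D; ++m) {
        const double* dyc =
            dyp + (static_cast<size_t>(b) * F * D + f * D + m) * L;
        for (int h = 0; h < H; ++h) {
          const size_t wi = (static_cast<size_t>(f) * D + m) * H + h;
          const double* xc =
              xp + ((static_cast<size_t>(b) * H + h) * F + f) * L;
          double acc = 0.0;
          for (int t = 0; t < L; ++t) acc += dyc[t] * xc[t];
          dwp[wi] += acc;
          if (need_dx) {
            double* dxc =
                dxp + ((static_cast<size_t>(b) * H + h) * F + f) * L;
            const double wv = wp[wi];
            for (int t = 0; t < L; ++t) dxc[t] += wv * dyc[t];
          }
        }
      }
  if (need_dx) dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
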