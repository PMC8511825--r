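// Low-level CNN primitives: im2col-based (dilated) convolution, transposed
// convolution, 2x2 max pooling with optional dilation, and per-pixel softmax
// cross-entropy.  All spatial tensors are R arrays in (H, W, C) column-major
// layout; convolution weights are (k, k, in, out) so that the flattened row
// index (ki + k*kj + k*k*ci) matches the im2col row order below.
//
// Every routine exists in float and double flavours ("single" is the training
// fast path on one CPU; "double" is the default inference path).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int s, int d, int p) {
  int keff = d * (k - 1) + 1;
  return (H + 2 * p - keff) / s + 1;
}

template <typename eT>
static void im2col(const arma::Mat<eT>& x, int H, int W, int C,
                   int k, int s, int d, int p, arma::Mat<eT>& cols) {
  // x: (H*W) x C.  cols: (k*k*C) x (Ho*Wo), column index = oy + Ho*ox.
  const int Ho = out_size(H, k, s, d, p);
  const int Wo = out_size(W, k, s, d, p);
  cols.zeros(k * k * C, (arma::uword)Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const eT* xc = x.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * s - p + kj * d;
          if (ix < 0 || ix >= W) continue;
          eT* dst = cols.colptr((arma::uword)ox * Ho) + r;
          const eT* src = xc + (arma::uword)ix * H;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * s - p + ki * d;
            if (iy >= 0 && iy < H) dst[(arma::uword)oy * cols.n_rows] = src[iy];
          }
        }
      }
    }
  }
}

template <typename eT>
static void col2im(const arma::Mat<eT>& cols, int H, int W, int C,
                   int k, int s, int d, int p, arma::Mat<eT>& x) {
  // adjoint of im2col: scatter-add columns back into the (H*W) x C image
  const int Ho = out_size(H, k, s, d, p);
  const int Wo = out_size(W, k, s, d, p);
  x.zeros((arma::uword)H * W, C);
  for (int c = 0; c < C; ++c) {
    eT* xc = x.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * s - p + kj * d;
          if (ix < 0 || ix >= W) continue;
          const eT* src = cols.colptr((arma::uword)ox * Ho) + r;
          eT* dst = xc + (arma::uword)ix * H;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * s - p + ki * d;
            if (iy >= 0 && iy < H) dst[iy] += src[(arma::uword)oy * cols.n_rows];
          }
        }
      }
    }
  }
}

template <typename eT>
static arma::Mat<eT> as_mat(const NumericVector& v, arma::uword nr, arma::uword nc) {
  arma::Mat<eT> m(nr, nc);
  const double* p = v.begin();
  eT* q = m.memptr();
  const arma::uword n = nr * nc;
  for (arma::uword i = 0; i < n; ++i) q[i] = (eT)p[i];
  return m;
}

static NumericVector to_r(const arma::Mat<float>& m, int H, int W, int C) {
  NumericVector out((R_xlen_t)H * W * C);
  const float* q = m.memptr();
  double* p = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) p[i] = (double)q[i];
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
static NumericVector to_r(const arma::Mat<double>& m, int H, int W, int C) {
  NumericVector out((R_xlen_t)H * W * C);
  std::copy(m.memptr(), m.memptr() + out.size(), out.begin());
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

template <typename eT>
static NumericVector conv_fwd_t(const NumericVector& x, IntegerVector dx,
                                const NumericVector& w, const NumericVector& b,
                                int k, int cin, int cout,
                                int s, int d, int p, bool relu) {
  const int H = dx[0], W = dx[1];
  arma::Mat<eT> xm = as_mat<eT>(x, (arma::uword)H * W, cin);
  arma::Mat<eT> wm = as_mat<eT>(w, (arma::uword)k * k * cin, cout);
  arma::Mat<eT> cols;
  im2col<eT>(xm, H, W, cin, k, s, d, p, cols);
  const int Ho = out_size(H, k, s, d, p), Wo = out_size(W, k, s, d, p);
  arma::Mat<eT> y = cols.t() * wm;  // (Ho*Wo) x cout
  for (int c = 0; c < cout; ++c) y.col(c) += (eT)b[c];
  if (relu) y.for_each([](eT& v) { if (v < 0) v = 0; });
  return to_r(y, Ho, Wo, cout);
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int s, int d, int p, bool relu, bool single) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  if (dx[2] != dw[2]) stop("conv: channel mismatch");
  if (single)
    return conv_fwd_t<float>(x, dx, w, b, dw[0], dw[2], dw[3], s, d, p, relu);
  return conv_fwd_t<double>(x, dx, w, b, dw[0], dw[2], dw[3], s, d, p, relu);
}

template <typename eT>
static List conv_bwd_t(const NumericVector& x, IntegerVector dx,
                       const NumericVector& w, const NumericVector& gy,
                       int k, int cin, int cout, int s, int d, int p,
                       bool need_gx) {
  const int H = dx[0], W = dx[1];
  const int Ho = out_size(H, k, s, d, p), Wo = out_size(W, k, s, d, p);
  arma::Mat<eT> xm = as_mat<eT>(x, (arma::uword)H * W, cin);
  arma::Mat<eT> wm = as_mat<eT>(w, (arma::uword)k * k * cin, cout);
  arma::Mat<eT> gym = as_mat<eT>(gy, (arma::uword)Ho * Wo, cout);
  arma::Mat<eT> cols;
  im2col<eT>(xm, H, W, cin, k, s, d, p, cols);
  arma::Mat<eT> gw = cols * gym;                      // (k*k*cin) x cout
  arma::Row<eT> gb = arma::sum(gym, 0);
  List out;
  NumericVector gwr(gw.memptr(), gw.memptr() + gw.n_elem);
  gwr.attr("dim") = IntegerVector::create(k, k, cin, cout);
  out["gw"] = gwr;
  out["gb"] = NumericVector(gb.memptr(), gb.memptr() + cout);
  if (need_gx) {
    arma::Mat<eT> gcols = wm * gym.t();               // (k*k*cin) x (Ho*Wo)
    arma::Mat<eT> gx;
    col2im<eT>(gcols, H, W, cin, k, s, d, p, gx);
    out["gx"] = to_r(gx, H, W, cin);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int s, int d, int p, bool need_gx, bool single) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  if (single)
    return conv_bwd_t<float>(x, dx, w, gy, dw[0], dw[2], dw[3], s, d, p, need_gx);
  return conv_bwd_t<double>(x, dx, w, gy, dw[0], dw[2], dw[3], s, d, p, need_gx);
}

// Transposed convolution: the adjoint of a (k, stride s, pad p) convolution.
// Weight array is (k, k, c_out, c_in): c_in channels in, c_out channels out.
template <typename eT>
static NumericVector tconv_fwd_t(const NumericVector& z, IntegerVector dz,
                                 const NumericVector& w, const NumericVector& b,
                                 int k, int cout, int cin, int s, int p) {
  const int Hs = dz[0], Ws = dz[1];
  const int Hb = (Hs - 1) * s - 2 * p + k, Wb = (Ws - 1) * s - 2 * p + k;
  arma::Mat<eT> zm = as_mat<eT>(z, (arma::uword)Hs * Ws, cin);
  arma::Mat<eT> wm = as_mat<eT>(w, (arma::uword)k * k * cout, cin);
  arma::Mat<eT> gcols = wm * zm.t();
  arma::Mat<eT> y;
  col2im<eT>(gcols, Hb, Wb, cout, k, s, 1, p, y);
  for (int c = 0; c < cout; ++c) y.col(c) += (eT)b[c];
  return to_r(y, Hb, Wb, cout);
}

// [[Rcpp::export]]
NumericVector cpp_tconv_fwd(NumericVector z, NumericVector w, NumericVector b,
                            int s, int p, bool single) {
  IntegerVector dz = z.attr("dim"), dw = w.attr("dim");
  if (dz[2] != dw[3]) stop("tconv: channel mismatch");
  if (single) return tconv_fwd_t<float>(z, dz, w, b, dw[0], dw[2], dw[3], s, p);
  return tconv_fwd_t<double>(z, dz, w, b, dw[0], dw[2], dw[3], s, p);
}

template <typename eT>
static List tconv_bwd_t(const NumericVector& z, IntegerVector dz,
                        const NumericVector& w, const NumericVector& gy,
                        int k, int cout, int cin, int s, int p) {
  const int Hs = dz[0], Ws = dz[1];
  const int Hb = (Hs - 1) * s - 2 * p + k, Wb = (Ws - 1) * s - 2 * p + k;
  arma::Mat<eT> zm = as_mat<eT>(z, (arma::uword)Hs * Ws, cin);
  arma::Mat<eT> wm = as_mat<eT>(w, (arma::uword)k * k * cout, cin);
  arma::Mat<eT> gym = as_mat<eT>(gy, (arma::uword)Hb * Wb, cout);
  arma::Mat<eT> cols;
  im2col<eT>(gym, Hb, Wb, cout, k, s, 1, p, cols);  // (k*k*cout) x (Hs*Ws)
  arma::Mat<eT> gz = cols.t() * wm;                 // (Hs*Ws) x cin
  arma::Mat<eT> gw = cols * zm;                     // (k*k*cout) x cin
  arma::Row<eT> gb = arma::sum(gym, 0);
  NumericVector gwr(gw.memptr(), gw.memptr() + gw.n_elem);
  gwr.attr("dim") = IntegerVector::create(k, k, cout, cin);
  return List::create(_["gz"] = to_r(gz, Hs, Ws, cin), _["gw"] = gwr,
                      _["gb"] = NumericVector(gb.memptr(), gb.memptr() + cout));
}

// [[Rcpp::export]]
List cpp_tconv_bwd(NumericVector z, NumericVector w, NumericVector gy,
                   int s, int p, bool single) {
  IntegerVector dz = z.attr("dim"), dw = w.attr("dim");
  if (single) return tconv_bwd_t<float>(z, dz, w, gy, dw[0], dw[2], dw[3], s, p);
  return tconv_bwd_t<double>(z, dz, w, gy, dw[0], dw[2], dw[3], s, p);
}

// 2x2 max pool.  stride 2: exact halving (even input assumed, no padding).
// stride 1 (a dilated, resolution-preserving pool): window elements are d
// apart, output size equals input size, out-of-range taps are ignored.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int s, int d) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2];
  const int Ho = (s == 2) ? H / 2 : H, Wo = (s == 2) ? W / 2 : W;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);  // 1-based linear index into x
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)c * H * W, yoff = (R_xlen_t)c * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        double best = R_NegInf;
        R_xlen_t bi = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int ix = ox * s + kj * d;
          if (ix >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int iy = oy * s + ki * d;
            if (iy >= H) continue;
            const R_xlen_t li = xoff + (R_xlen_t)ix * H + iy;
            if (xp[li] > best) { best = xp[li]; bi = li; }
          }
        }
        y[yoff + (R_xlen_t)ox * Ho + oy] = best;
        idx[yoff + (R_xlen_t)ox * Ho + oy] = (int)(bi + 1);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gy,
                              int H, int W, int C) {
  NumericVector gx((R_xlen_t)H * W * C);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// Per-pixel softmax cross-entropy.  labels: (H, W) integers in 0..C-1;
// cw: per-class weights (length C).  Returns mean weighted loss and the
// gradient w.r.t. the score maps (already divided by the weighted pixel sum).
// [[Rcpp::export]]
List cpp_softmax_xent(NumericVector scores, IntegerVector labels,
                      NumericVector cw) {
  IntegerVector ds = scores.attr("dim");
  const int H = ds[0], W = ds[1], C = ds[2];
  const R_xlen_t N = (R_xlen_t)H * W;
  NumericVector grad((R_xlen_t)H * W * C);
  double loss = 0.0, wsum = 0.0;
  std::vector<double> pr(C);
  for (R_xlen_t i = 0; i < N; ++i) {
    double mx = R_NegInf;
    for (int c = 0; c < C; ++c) mx = std::max(mx, scores[i + c * N]);
    double z = 0.0;
    for (int c = 0; c < C; ++c) { pr[c] = std::exp(scores[i + c * N] - mx); z += pr[c]; }
    const int lab = labels[i];
    const double wgt = cw[lab];
    loss += -wgt * (std::log(pr[lab]) - std::log(z));
    wsum += wgt;
    for (int c = 0; c < C; ++c) {
      grad[i + c * N] = wgt * (pr[c] / z - (c == lab ? 1.0 : 0.0));
    }
  }
  if (wsum > 0) {
    for (R_xlen_t i = 0; i < grad.size(); ++i) grad[i] /= wsum;
    loss /= wsum;
  }
  grad.attr("dim") = ds;
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
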