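// Dense-prediction kernels: 2-D convolution, transposed convolution,
// bilinear resizing and RoIAlign, each with an explicit backward pass.
//
// Feature maps are R arrays dim c(H, W, C) (column-major, so a map is an
// (H*W) x C matrix in memory); weights are arrays dim c(kh, kw, Cin, Cout).
// Convolutions are computed as a sum over kernel offsets of strided-slice
// matrix products, which keeps peak memory at one extra map (no im2col
// buffer) — important for the 256-channel pyramid of a full-size image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void offset_range(int n_in, int n_out, int stride, int pad,
                                int k, int& lo, int& hi) {
  // valid out positions o with 0 <= stride*o + k - pad <= n_in - 1
  lo = (int)std::ceil((double)(pad - k) / stride);
  hi = (int)std::floor((double)(n_in - 1 + pad - k) / stride);
  if (lo < 0) lo = 0;
  if (hi > n_out - 1) hi = n_out - 1;
}

static void offset_indices(int H, int W, int Ho, int Wo, int stride, int pad,
                           int ki, int kj, arma::uvec& in_idx,
                           arma::uvec& out_idx) {
  int ilo, ihi, jlo, jhi;
  offset_range(H, Ho, stride, pad, ki, ilo, ihi);
  offset_range(W, Wo, stride, pad, kj, jlo, jhi);
  if (ihi < ilo || jhi < jlo) { in_idx.reset(); out_idx.reset(); return; }
  int ni = ihi - ilo + 1, nj = jhi - jlo + 1;
  in_idx.set_size((arma::uword)ni * nj);
  out_idx.set_size((arma::uword)ni * nj);
  arma::uword t = 0;
  for (int oj = jlo; oj <= jhi; ++oj) {
    int jj = stride * oj + kj - pad;
    for (int oi = ilo; oi <= ihi; ++oi) {
      int ii = stride * oi + ki - pad;
      in_idx[t] = (arma::uword)(ii + jj * H);
      out_idx[t] = (arma::uword)(oi + oj * Ho);
      ++t;
    }
  }
}

static arma::mat kernel_slice(const NumericVector& w, int kh, int kw,
                              int cin, int cout, int ki, int kj) {
  arma::mat Wk(cin, cout);
  const double* p = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      Wk(ci, co) = p[ki + kj * kh + ci * kh * kw + co * kh * kw * cin];
  return Wk;
}

static IntegerVector dims_of(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  arma::mat X(x.begin(), (arma::uword)H * W, Cin, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout);
  arma::mat Y(out.begin(), (arma::uword)Ho * Wo, Cout, false, true);
  for (int c = 0; c < Cout; ++c) Y.col(c).fill(bias[c]);
  arma::uvec in_idx, out_idx;
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      offset_indices(H, W, Ho, Wo, stride, pad, ki, kj, in_idx, out_idx);
      if (in_idx.n_elem == 0) continue;
      arma::mat Wk = kernel_slice(w, kh, kw, Cin, Cout, ki, kj);
      Y.rows(out_idx) += X.rows(in_idx) * Wk;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat X(x.begin(), (arma::uword)H * W, Cin, false, true);
  arma::mat dY(dy.begin(), (arma::uword)Ho * Wo, Cout, false, true);
  NumericVector dxv((R_xlen_t)H * W * Cin);
  arma::mat dX(dxv.begin(), (arma::uword)H * W, Cin, false, true);
  NumericVector dwv((R_xlen_t)kh * kw * Cin * Cout);
  NumericVector dbv(Cout);
  arma::rowvec db = arma::sum(dY, 0);
  for (int c = 0; c < Cout; ++c) dbv[c] = db[c];
  arma::uvec in_idx, out_idx;
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      offset_indices(H, W, Ho, Wo, stride, pad, ki, kj, in_idx, out_idx);
      if (in_idx.n_elem == 0) continue;
      arma::mat Wk = kernel_slice(w, kh, kw, Cin, Cout, ki, kj);
      arma::mat dYs = dY.rows(out_idx);
      dX.rows(in_idx) += dYs * Wk.t();
      arma::mat dWk = X.rows(in_idx).t() * dYs;
      double* p = dwv.begin();
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          p[ki + kj * kh + ci * kh * kw + co * kh * kw * Cin] = dWk(ci, co);
    }
  dxv.attr("dim") = IntegerVector::create(H, W, Cin);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Transposed convolution: out[stride*i + k - pad] += in[i] * W_k.
// Output size (n_in - 1)*stride - 2*pad + kernel.

// [[Rcpp::export(name = ".cpp_convt2d_fwd")]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w,
                              NumericVector bias, int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv_transpose2d: channel mismatch");
  int Ho = (H - 1) * stride - 2 * pad + kh;
  int Wo = (W - 1) * stride - 2 * pad + kw;
  if (Ho < 1 || Wo < 1) stop("conv_transpose2d: output would be empty");
  arma::mat X(x.begin(), (arma::uword)H * W, Cin, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout);
  arma::mat Y(out.begin(), (arma::uword)Ho * Wo, Cout, false, true);
  for (int c = 0; c < Cout; ++c) Y.col(c).fill(bias[c]);
  arma::uvec in_idx, out_idx;
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      // roles of input/output swap relative to conv2d
      offset_indices(Ho, Wo, H, W, stride, pad, ki, kj, out_idx, in_idx);
      if (in_idx.n_elem == 0) continue;
      arma::mat Wk = kernel_slice(w, kh, kw, Cin, Cout, ki, kj);
      Y.rows(out_idx) += X.rows(in_idx) * Wk;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".cpp_convt2d_bwd")]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat X(x.begin(), (arma::uword)H * W, Cin, false, true);
  arma::mat dY(dy.begin(), (arma::uword)Ho * Wo, Cout, false, true);
  NumericVector dxv((R_xlen_t)H * W * Cin);
  arma::mat dX(dxv.begin(), (arma::uword)H * W, Cin, false, true);
  NumericVector dwv((R_xlen_t)kh * kw * Cin * Cout);
  NumericVector dbv(Cout);
  arma::rowvec db = arma::sum(dY, 0);
  for (int c = 0; c < Cout; ++c) dbv[c] = db[c];
  arma::uvec in_idx, out_idx;
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      offset_indices(Ho, Wo, H, W, stride, pad, ki, kj, out_idx, in_idx);
      if (in_idx.n_elem == 0) continue;
      arma::mat Wk = kernel_slice(w, kh, kw, Cin, Cout, ki, kj);
      arma::mat dYs = dY.rows(out_idx);
      dX.rows(in_idx) += dYs * Wk.t();
      arma::mat dWk = X.rows(in_idx).t() * dYs;
      double* p = dwv.begin();
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          p[ki + kj * kh + ci * kh * kw + co * kh * kw * Cin] = dWk(ci, co);
    }
  dxv.attr("dim") = IntegerVector::create(H, W, Cin);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Bilinear resize with half-pixel-center sampling: source coordinate of
// output cell o is (o + 0.5) * n_in / n_out - 0.5, clamped to the grid.

struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> w1;  // weight of i1; weight of i0 is 1 - w1
};

static AxisMap axis_map(int n_in, int n_out) {
  AxisMap m;
  m.i0.resize(n_out); m.i1.resize(n_out); m.w1.resize(n_out);
  double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    if (i0 > n_in - 1) i0 = n_in - 1;
    int i1 = std::min(i0 + 1, n_in - 1);
    m.i0[o] = i0; m.i1[o] = i1; m.w1[o] = s - i0;
  }
  return m;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_fwd")]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int oh, int ow) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2];
  AxisMap my = axis_map(H, oh), mx = axis_map(W, ow);
  NumericVector out((R_xlen_t)oh * ow * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (R_xlen_t)c * H * W;
    double* oc = po + (R_xlen_t)c * oh * ow;
    for (int oj = 0; oj < ow; ++oj) {
      int j0 = mx.i0[oj], j1 = mx.i1[oj];
      double wx = mx.w1[oj];
      for (int oi = 0; oi < oh; ++oi) {
        int i0 = my.i0[oi], i1 = my.i1[oi];
        double wy = my.w1[oi];
        double v00 = xc[i0 + j0 * H], v10 = xc[i1 + j0 * H];
        double v01 = xc[i0 + j1 * H], v11 = xc[i1 + j1 * H];
        oc[oi + oj * oh] = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                           wy * ((1 - wx) * v10 + wx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  return out;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_bwd")]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dims_of(dy);
  int oh = yd[0], ow = yd[1], C = yd[2];
  AxisMap my = axis_map(H, oh), mx = axis_map(W, ow);
  NumericVector dx((R_xlen_t)H * W * C);
  const double* pd = dy.begin();
  double* px = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dc = pd + (R_xlen_t)c * oh * ow;
    double* xc = px + (R_xlen_t)c * H * W;
    for (int oj = 0; oj < ow; ++oj) {
      int j0 = mx.i0[oj], j1 = mx.i1[oj];
      double wx = mx.w1[oj];
      for (int oi = 0; oi < oh; ++oi) {
        int i0 = my.i0[oi], i1 = my.i1[oi];
        double wy = my.w1[oi];
        double g = dc[oi + oj * oh];
        xc[i0 + j0 * H] += (1 - wy) * (1 - wx) * g;
        xc[i0 + j1 * H] += (1 - wy) * wx * g;
        xc[i1 + j0 * H] += wy * (1 - wx) * g;
        xc[i1 + j1 * H] += wy * wx * g;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// RoIAlign: rois are n x 4 (x1, y1, x2, y2) in continuous feature-grid
// index coordinates (image coordinate / stride - 0.5, so integer index i
// is the center of cell i). Each output bin averages a 2x2 grid of
// bilinear samples.

static inline void bilin_coef(double s, int n, int& i0, int& i1, double& w1,
                              bool& valid) {
  if (s < -1.0 || s > (double)n) { valid = false; return; }
  valid = true;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  if (i0 > n - 1) i0 = n - 1;
  i1 = std::min(i0 + 1, n - 1);
  w1 = s - i0;
}

// [[Rcpp::export(name = ".cpp_roi_align_fwd")]]
NumericVector cpp_roi_align_fwd(NumericVector x, NumericMatrix rois,
                                int out_size) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2];
  int n = rois.nrow();
  const int ns = 2;  // sampling points per bin per axis
  NumericVector out((R_xlen_t)out_size * out_size * C * n);
  const double* px = x.begin();
  double* po = out.begin();
  for (int r = 0; r < n; ++r) {
    double x1 = rois(r, 0), y1 = rois(r, 1), x2 = rois(r, 2), y2 = rois(r, 3);
    double bw = (x2 - x1) / out_size, bh = (y2 - y1) / out_size;
    for (int bj = 0; bj < out_size; ++bj) {
      for (int bi = 0; bi < out_size; ++bi) {
        double acc_w = 0.0;
        // accumulate per-channel into output cell
        R_xlen_t obase = bi + (R_xlen_t)bj * out_size;
        for (int sy = 0; sy < ns; ++sy) {
          double yy = y1 + (bi + (sy + 0.5) / ns) * bh;
          int i0, i1; double wy; bool vy;
          bilin_coef(yy, H, i0, i1, wy, vy);
          if (!vy) continue;
          for (int sx = 0; sx < ns; ++sx) {
            double xx = x1 + (bj + (sx + 0.5) / ns) * bw;
            int j0, j1; double wx; bool vx;
            bilin_coef(xx, W, j0, j1, wx, vx);
            if (!vx) continue;
            acc_w += 1.0;
            for (int c = 0; c < C; ++c) {
              const double* xc = px + (R_xlen_t)c * H * W;
              double v = (1 - wy) * ((1 - wx) * xc[i0 + j0 * H] +
                                     wx * xc[i0 + j1 * H]) +
                         wy * ((1 - wx) * xc[i1 + j0 * H] +
                               wx * xc[i1 + j1 * H]);
              po[obase + (R_xlen_t)c * out_size * out_size +
                 (R_xlen_t)r * out_size * out_size * C] += v;
            }
          }
        }
        if (acc_w > 0) {
          for (int c = 0; c < C; ++c)
            po[obase + (R_xlen_t)c * out_size * out_size +
               (R_xlen_t)r * out_size * out_size * C] /= (double)(ns * ns);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(out_size, out_size, C, n);
  return out;
}

// [[Rcpp::export(name = ".cpp_roi_align_bwd")]]
NumericVector cpp_roi_align_bwd(NumericVector dy, NumericMatrix rois,
                                int H, int W) {
  IntegerVector yd = dims_of(dy);
  int out_size = yd[0], C = yd[2];
  int n = rois.nrow();
  const int ns = 2;
  NumericVector dx((R_xlen_t)H * W * C);
  double* px = dx.begin();
  const double* pd = dy.begin();
  for (int r = 0; r < n; ++r) {
    double x1 = rois(r, 0), y1 = rois(r, 1), x2 = rois(r, 2), y2 = rois(r, 3);
    double bw = (x2 - x1) / out_size, bh = (y2 - y1) / out_size;
    for (int bj = 0; bj < out_size; ++bj) {
      for (int bi = 0; bi < out_size; ++bi) {
        R_xlen_t obase = bi + (R_xlen_t)bj * out_size;
        for (int sy = 0; sy < ns; ++sy) {
          double yy = y1 + (bi + (sy + 0.5) / ns) * bh;
          int i0, i1; double wy; bool vy;
          bilin_coef(yy, H, i0, i1, wy, vy);
          if (!vy) continue;
          for (int sx = 0; sx < ns; ++sx) {
            double xx = x1 + (bj + (sx + 0.5) / ns) * bw;
            int j0, j1; double wx; bool vx;
            bilin_coef(xx, W, j0, j1, wx, vx);
            if (!vx) continue;
            for (int c = 0; c < C; ++c) {
              double g = pd[obase + (R_xlen_t)c * out_size * out_size +
                            (R_xlen_t)r * out_size * out_size * C] /
                         (double)(ns * ns);
              double* xc = px + (R_xlen_t)c * H * W;
              xc[i0 + j0 * H] += (1 - wy) * (1 - wx) * g;
              xc[i0 + j1 * H] += (1 - wy) * wx * g;
              xc[i1 + j0 * H] += wy * (1 - wx) * g;
              xc[i1 + j1 * H] += wy * wx * g;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
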