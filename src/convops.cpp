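// im2col / col2im convolution core. Arrays are column-major with the channel
// axis last: 2D (H, W, C), 3D (D, H, W, C). Kernel offsets are enumerated
// lexicographically with the first spatial axis slowest, matching the R-side
// weight layout (rows grouped by offset, channel fastest within a group).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// padded input -> (n, k^nd * C) matrix; xp dims = padded spatial + C
// [[Rcpp::export(name = ".im2col_cpp")]]
arma::mat im2col_cpp(const arma::vec &xp, IntegerVector padded_sp,
                     IntegerVector out_sp, int C, int k) {
  int nd = out_sp.size();
  if (nd == 2) {
    int Hp = padded_sp[0], Wp = padded_sp[1], H = out_sp[0], W = out_sp[1];
    arma::uword n = (arma::uword)H * W;
    arma::mat Xm(n, (arma::uword)k * k * C);
    for (int o1 = 0; o1 < k; ++o1)
      for (int o2 = 0; o2 < k; ++o2)
        for (int c = 0; c < C; ++c) {
          arma::uword col = ((arma::uword)o1 * k + o2) * C + c;
          const double *src = xp.memptr() + (arma::uword)c * Hp * Wp;
          double *dst = Xm.colptr(col);
          for (int x0 = 0; x0 < W; ++x0) {
            const double *s = src + (arma::uword)(x0 + o2) * Hp + o1;
            double *d = dst + (arma::uword)x0 * H;
            std::copy(s, s + H, d);
          }
        }
    return Xm;
  }
  int Dp = padded_sp[0], Hp = padded_sp[1], Wp = padded_sp[2];
  int D = out_sp[0], H = out_sp[1], W = out_sp[2];
  arma::uword n = (arma::uword)D * H * W;
  arma::mat Xm(n, (arma::uword)k * k * k * C);
  for (int o1 = 0; o1 < k; ++o1)
    for (int o2 = 0; o2 < k; ++o2)
      for (int o3 = 0; o3 < k; ++o3)
        for (int c = 0; c < C; ++c) {
          arma::uword col = (((arma::uword)o1 * k + o2) * k + o3) * C + c;
          const double *src = xp.memptr() + (arma::uword)c * Dp * Hp * Wp;
          double *dst = Xm.colptr(col);
          for (int x0 = 0; x0 < W; ++x0)
            for (int y0 = 0; y0 < H; ++y0) {
              const double *s = src + ((arma::uword)(x0 + o3) * Hp + (y0 + o2)) * Dp + o1;
              double *d = dst + ((arma::uword)x0 * H + y0) * D;
              std::copy(s, s + D, d);
            }
        }
  return Xm;
}

// scatter-add of column blocks back onto the padded gradient array
// [[Rcpp::export(name = ".col2im_cpp")]]
arma::vec col2im_cpp(const arma::mat &dcols, IntegerVector padded_sp,
                     IntegerVector out_sp, int C, int k) {
  int nd = out_sp.size();
  if (nd == 2) {
    int Hp = padded_sp[0], Wp = padded_sp[1], H = out_sp[0], W = out_sp[1];
    arma::vec dxp((arma::uword)Hp * Wp * C, arma::fill::zeros);
    for (int o1 = 0; o1 < k; ++o1)
      for (int o2 = 0; o2 < k; ++o2)
        for (int c = 0; c < C; ++c) {
          arma::uword col = ((arma::uword)o1 * k + o2) * C + c;
          const double *src = dcols.colptr(col);
          double *dst = dxp.memptr() + (arma::uword)c * Hp * Wp;
          for (int x0 = 0; x0 < W; ++x0) {
            const double *s = src + (arma::uword)x0 * H;
            double *d = dst + (arma::uword)(x0 + o2) * Hp + o1;
            for (int y0 = 0; y0 < H; ++y0) d[y0] += s[y0];
          }
        }
    return dxp;
  }
  int Dp = padded_sp[0], Hp = padded_sp[1], Wp = padded_sp[2];
  int D = out_sp[0], H = out_sp[1], W = out_sp[2];
  arma::vec dxp((arma::uword)Dp * Hp * Wp * C, arma::fill::zeros);
  for (int o1 = 0; o1 < k; ++o1)
    for (int o2 = 0; o2 < k; ++o2)
      for (int o3 = 0; o3 < k; ++o3)
        for (int c = 0; c < C; ++c) {
          arma::uword col = (((arma::uword)o1 * k + o2) * k + o3) * C + c;
          const double *src = dcols.colptr(col);
          double *dst = dxp.memptr() + (arma::uword)c * Dp * Hp * Wp;
          for (int x0 = 0; x0 < W; ++x0)
            for (int y0 = 0; y0 < H; ++y0) {
              const double *s = src + ((arma::uword)x0 * H + y0) * D;
              double *d = dst + ((arma::uword)(x0 + o3) * Hp + (y0 + o2)) * Dp + o1;
              for (int z0 = 0; z0 < D; ++z0) d[z0] += s[z0];
            }
        }
  return dxp;
}

// zero-pad every spatial axis by p (channel axis last)
// [[Rcpp::export(name = ".pad_zero_cpp")]]
arma::vec pad_zero_cpp(const arma::vec &x, IntegerVector sp, int C, int p) {
  int nd = sp.size();
  if (nd == 2) {
    int H = sp[0], W = sp[1], Hp = H + 2 * p, Wp = W + 2 * p;
    arma::vec y((arma::uword)Hp * Wp * C, arma::fill::zeros);
    for (int c = 0; c < C; ++c)
      for (int x0 = 0; x0 < W; ++x0) {
        const double *s = x.memptr() + ((arma::uword)c * W + x0) * H;
        double *d = y.memptr() + (arma::uword)c * Hp * Wp +
                    (arma::uword)(x0 + p) * Hp + p;
        std::copy(s, s + H, d);
      }
    return y;
  }
  int D = sp[0], H = sp[1], W = sp[2];
  int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  arma::vec y((arma::uword)Dp * Hp * Wp * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int x0 = 0; x0 < W; ++x0)
      for (int y0 = 0; y0 < H; ++y0) {
        const double *s = x.memptr() +
                          (((arma::uword)c * W + x0) * H + y0) * D;
        double *d = y.memptr() + (arma::uword)c * Dp * Hp * Wp +
                    ((arma::uword)(x0 + p) * Hp + (y0 + p)) * Dp + p;
        std::copy(s, s + D, d);
      }
  return y;
}

// Weighted patch merge: out[v] = sum_i w(v_i) p_i(v) / sum_i w(v_i).
// Accumulates in extended precision so that merging identical overlapping
// values reproduces them bit-exactly (sequential double accumulation of
// c copies of x rounds for odd c). patches: one column per grid box;
// starts: 0-based (row per box); dims are zero-padded to length 3.
// [[Rcpp::export(name = ".merge_patches_cpp")]]
NumericVector merge_patches_cpp(const NumericMatrix &patches,
                                const IntegerMatrix &starts,
                                IntegerVector patch_dim3,
                                IntegerVector out_dim3,
                                const NumericVector &w) {
  int pd = patch_dim3[0], ph = patch_dim3[1], pw = patch_dim3[2];
  int od = out_dim3[0], oh = out_dim3[1], ow = out_dim3[2];
  R_xlen_t n = (R_xlen_t)od * oh * ow;
  std::vector<long double> num(n, 0.0L), den(n, 0.0L);
  for (int b = 0; b < starts.nrow(); ++b) {
    int sz = starts(b, 0), sy = starts(b, 1), sx = starts(b, 2);
    for (int x = 0; x < pw; ++x)
      for (int y = 0; y < ph; ++y)
        for (int z = 0; z < pd; ++z) {
          R_xlen_t pi = ((R_xlen_t)x * ph + y) * pd + z;
          R_xlen_t oi = ((R_xlen_t)(sx + x) * oh + (sy + y)) * od + (sz + z);
          long double wt = w[pi];
          num[oi] += wt * (long double)patches(pi, b);
          den[oi] += wt;
        }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (den[i] == 0.0L) stop("malformed grid: some voxels are uncovered");
    out[i] = (double)(num[i] / den[i]);
  }
  return out;
}

// ELU (alpha = 1) forward and backward (derivative via the cached output)
// [[Rcpp::export(name = ".elu_fwd_cpp")]]
NumericVector elu_fwd_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  for (R_xlen_t i = 0; i < n; ++i)
    y[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return y;
}

// [[Rcpp::export(name = ".elu_bwd_cpp")]]
NumericVector elu_bwd_cpp(NumericVector dy, NumericVector y) {
  R_xlen_t n = y.size();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i)
    d[i] = y[i] > 0 ? dy[i] : dy[i] * (y[i] + 1.0);
  return d;
}

// crop the padded margin back off (inverse of pad_zero_cpp)
// [[Rcpp::export(name = ".crop_pad_cpp")]]
arma::vec crop_pad_cpp(const arma::vec &xp, IntegerVector sp, int C, int p) {
  int nd = sp.size();
  if (nd == 2) {
    int H = sp[0], W = sp[1], Hp = H + 2 * p, Wp = W + 2 * p;
    arma::vec y((arma::uword)H * W * C);
    for (int c = 0; c < C; ++c)
      for (int x0 = 0; x0 < W; ++x0) {
        const double *s = xp.memptr() + (arma::uword)c * Hp * Wp +
                          (arma::uword)(x0 + p) * Hp + p;
        double *d = y.memptr() + ((arma::uword)c * W + x0) * H;
        std::copy(s, s + H, d);
      }
    return y;
  }
  int D = sp[0], H = sp[1], W = sp[2];
  int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  arma::vec y((arma::uword)D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int x0 = 0; x0 < W; ++x0)
      for (int y0 = 0; y0 < H; ++y0) {
        const double *s = xp.memptr() + (arma::uword)c * Dp * Hp * Wp +
                          ((arma::uword)(x0 + p) * Hp + (y0 + p)) * Dp + p;
        double *d = y.memptr() + (((arma::uword)c * W + x0) * H + y0) * D;
        std::copy(s, s + D, d);
      }
  return y;
}
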