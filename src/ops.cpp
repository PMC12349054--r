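// Low-level layer kernels. All feature maps are R arrays with dim (H, W, C),
// mapped onto arma::cube without copying. Convolutions are cross-correlations
// (deep-learning convention) with implicit zero padding and stride 1, so
// spatial dimensions are preserved for odd kernels with pad = (K-1)/2.
//
// Dense convolution weights are passed flattened as a (K*K*Cin) x Cout matrix
// whose row index is kh + K*(kw + K*cin) (0-based), i.e. the natural
// column-major flattening of an R array with dim (K, K, Cin, Cout).
//
// Deformable convolution offsets are an (H, W, 2*K*K) array: for tap
// t = kh + K*kw, slice 2t holds the row displacement (dy) and slice 2t+1 the
// column displacement (dx), in pixels. Sampling outside [0,H-1]x[0,W-1] reads
// an implicit zero border, matching the zero padding of the dense branch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

static cube as_cube(NumericVector x) {
  IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

static NumericVector wrap_cube(const cube& y) {
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(y.n_rows, y.n_cols, y.n_slices);
  return out;
}

static mat im2col(const cube& x, int K, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(K * K * C, (uword)H * W, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const int r = kh + K * (kw + K * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + kh - pad;
            if (si < 0 || si >= H) continue;
            col(r, i + (uword)H * j) = x(si, sj, c);
          }
        }
      }
  return col;
}

static void col2im_add(cube& gx, const mat& gcol, int K, int pad) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const int r = kh + K * (kw + K * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + kh - pad;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += gcol(r, i + (uword)H * j);
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, const arma::mat& wmat,
                             const arma::vec& bias, int K, int pad) {
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols;
  const int Cout = wmat.n_cols;
  mat col = im2col(xc, K, pad);
  mat ym = wmat.t() * col;  // Cout x (H*W)
  ym.each_col() += bias;
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = reshape(ym.row(c).t(), H, W);
  return wrap_cube(y);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, const arma::mat& wmat, NumericVector gy,
                    int K, int pad) {
  cube xc = as_cube(x), gyc = as_cube(gy);
  const int H = xc.n_rows, W = xc.n_cols, Cin = xc.n_slices;
  const int Cout = gyc.n_slices;
  mat gym(Cout, (uword)H * W);
  for (int c = 0; c < Cout; ++c)
    gym.row(c) = vectorise(gyc.slice(c)).t();
  mat col = im2col(xc, K, pad);
  mat gw = col * gym.t();                // (K*K*Cin) x Cout
  vec gb = sum(gym, 1);
  mat gcol = wmat * gym;                 // (K*K*Cin) x (H*W)
  cube gx(H, W, Cin, fill::zeros);
  col2im_add(gx, gcol, K, pad);
  return List::create(Named("gx") = wrap_cube(gx), Named("gw") = gw,
                      Named("gb") = NumericVector(gb.begin(), gb.end()));
}

// Depthwise convolution: one K x K kernel per channel, w is (K*K) x C with
// row index kh + K*kw.
// [[Rcpp::export]]
NumericVector cpp_depthwise_fwd(NumericVector x, const arma::mat& w,
                                const arma::vec& bias, int K, int pad) {
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  cube y(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const double wv = w(kh + K * kw, c);
        if (wv == 0.0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + kh - pad;
            if (si < 0 || si >= H) continue;
            y(i, j, c) += wv * xc(si, sj, c);
          }
        }
      }
    y.slice(c) += bias(c);
  }
  return wrap_cube(y);
}

// [[Rcpp::export]]
List cpp_depthwise_bwd(NumericVector x, const arma::mat& w, NumericVector gy,
                       int K, int pad) {
  cube xc = as_cube(x), gyc = as_cube(gy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  cube gx(H, W, C, fill::zeros);
  mat gw(K * K, C, fill::zeros);
  vec gb(C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    gb(c) = accu(gyc.slice(c));
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const double wv = w(kh + K * kw, c);
        double acc = 0.0;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + kh - pad;
            if (si < 0 || si >= H) continue;
            const double g = gyc(i, j, c);
            acc += g * xc(si, sj, c);
            gx(si, sj, c) += wv * g;
          }
        }
        gw(kh + K * kw, c) = acc;
      }
  }
  return List::create(Named("gx") = wrap_cube(gx), Named("gw") = gw,
                      Named("gb") = NumericVector(gb.begin(), gb.end()));
}

// Bilinear read with zero border; also returns corner metadata via pointers.
static inline double bilin(const cube& x, int c, double p, double q,
                           int H, int W) {
  const int i0 = (int)std::floor(p), j0 = (int)std::floor(q);
  const double fy = p - i0, fx = q - j0;
  double v = 0.0;
  for (int di = 0; di <= 1; ++di)
    for (int dj = 0; dj <= 1; ++dj) {
      const int ii = i0 + di, jj = j0 + dj;
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      const double wgt = (di ? fy : 1.0 - fy) * (dj ? fx : 1.0 - fx);
      v += wgt * x(ii, jj, c);
    }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericVector x, const arma::mat& pts) {
  // pts: n x 2 matrix of (row, col) 0-based real coordinates; returns n x C.
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int n = pts.n_rows;
  mat out(n, C);
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < C; ++c)
      out(k, c) = bilin(xc, c, pts(k, 0), pts(k, 1), H, W);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(n, C);
  return res;
}

static mat deform_col(const cube& x, const cube& off, int K, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(K * K * C, (uword)H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const uword l = i + (uword)H * j;
      for (int kw = 0; kw < K; ++kw)
        for (int kh = 0; kh < K; ++kh) {
          const int t = kh + K * kw;
          const double p = i + kh - pad + off(i, j, 2 * t);
          const double q = j + kw - pad + off(i, j, 2 * t + 1);
          for (int c = 0; c < C; ++c)
            col(t + K * K * c, l) = bilin(x, c, p, q, H, W);
        }
    }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_deform_fwd(NumericVector x, const arma::mat& wmat,
                             const arma::vec& bias, NumericVector off,
                             int K, int pad) {
  cube xc = as_cube(x), offc = as_cube(off);
  const int H = xc.n_rows, W = xc.n_cols;
  const int Cout = wmat.n_cols;
  mat col = deform_col(xc, offc, K, pad);
  mat ym = wmat.t() * col;
  ym.each_col() += bias;
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = reshape(ym.row(c).t(), H, W);
  return wrap_cube(y);
}

// [[Rcpp::export]]
List cpp_deform_bwd(NumericVector x, const arma::mat& wmat, NumericVector off,
                    NumericVector gy, int K, int pad) {
  cube xc = as_cube(x), offc = as_cube(off), gyc = as_cube(gy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Cout = gyc.n_slices;
  mat gym(Cout, (uword)H * W);
  for (int c = 0; c < Cout; ++c)
    gym.row(c) = vectorise(gyc.slice(c)).t();
  mat col = deform_col(xc, offc, K, pad);
  mat gw = col * gym.t();
  vec gb = sum(gym, 1);
  mat gcol = wmat * gym;  // (K*K*C) x (H*W)
  cube gx(H, W, C, fill::zeros);
  cube goff(H, W, 2 * K * K, fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const uword l = i + (uword)H * j;
      for (int kw = 0; kw < K; ++kw)
        for (int kh = 0; kh < K; ++kh) {
          const int t = kh + K * kw;
          const double p = i + kh - pad + offc(i, j, 2 * t);
          const double q = j + kw - pad + offc(i, j, 2 * t + 1);
          const int i0 = (int)std::floor(p), j0 = (int)std::floor(q);
          const double fy = p - i0, fx = q - j0;
          double gdy = 0.0, gdx = 0.0;
          for (int c = 0; c < C; ++c) {
            const double g = gcol(t + K * K * c, l);
            if (g == 0.0) continue;
            double v[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
            for (int di = 0; di <= 1; ++di)
              for (int dj = 0; dj <= 1; ++dj) {
                const int ii = i0 + di, jj = j0 + dj;
                if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
                v[di][dj] = xc(ii, jj, c);
                const double wgt =
                    (di ? fy : 1.0 - fy) * (dj ? fx : 1.0 - fx);
                gx(ii, jj, c) += g * wgt;
              }
            gdy += g * ((v[1][0] - v[0][0]) * (1.0 - fx) +
                        (v[1][1] - v[0][1]) * fx);
            gdx += g * ((v[0][1] - v[0][0]) * (1.0 - fy) +
                        (v[1][1] - v[1][0]) * fy);
          }
          goff(i, j, 2 * t) += gdy;
          goff(i, j, 2 * t + 1) += gdx;
        }
    }
  return List::create(Named("gx") = wrap_cube(gx), Named("gw") = gw,
                      Named("gb") = NumericVector(gb.begin(), gb.end()),
                      Named("goff") = wrap_cube(goff));
}

// 2x2 max pooling, stride 2. Returns pooled map and 1-based argmax linear
// indices into the input array.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  IntegerVector idx((uword)Ho * Wo * C);
  uword k = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bestl = 0;
        for (int dj = 0; dj <= 1; ++dj)
          for (int di = 0; di <= 1; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = xc(ii, jj, c);
            if (v > best) {
              best = v;
              bestl = ii + (uword)H * jj + (uword)H * W * c;
            }
          }
        y(i, j, c) = best;
        idx[k++] = (int)bestl + 1;
      }
  return List::create(Named("y") = wrap_cube(y), Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               int H, int W, int C) {
  cube gx(H, W, C, fill::zeros);
  const double* g = gy.begin();
  for (int k = 0; k < idx.size(); ++k)
    gx(idx[k] - 1) += g[k];
  return wrap_cube(gx);
}

// Bilinear resize (align_corners = TRUE); linear map, so the backward pass is
// the transpose scatter of the forward gather.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const double sy = Ho > 1 ? (double)(H - 1) / (Ho - 1) : 0.0;
  const double sx = Wo > 1 ? (double)(W - 1) / (Wo - 1) : 0.0;
  cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = bilin(xc, c, i * sy, j * sx, H, W);
  return wrap_cube(y);
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, int H, int W) {
  cube gyc = as_cube(gy);
  const int Ho = gyc.n_rows, Wo = gyc.n_cols, C = gyc.n_slices;
  const double sy = Ho > 1 ? (double)(H - 1) / (Ho - 1) : 0.0;
  const double sx = Wo > 1 ? (double)(W - 1) / (Wo - 1) : 0.0;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double p = i * sy, q = j * sx;
        const int i0 = (int)std::floor(p), j0 = (int)std::floor(q);
        const double fy = p - i0, fx = q - j0;
        const double g = gyc(i, j, c);
        for (int di = 0; di <= 1; ++di)
          for (int dj = 0; dj <= 1; ++dj) {
            const int ii = i0 + di, jj = j0 + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            gx(ii, jj, c) += g * (di ? fy : 1.0 - fy) * (dj ? fx : 1.0 - fx);
          }
      }
  return wrap_cube(gx);
}
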