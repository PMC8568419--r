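// Layer kernels for the U-Net: same-padded k x k convolution, 2x2 max pooling
// (stride 2), 2x2 transposed convolution (stride 2), and an affine image
// warper.  Feature maps are arma::cube with dimensions (H, W, C); convolution
// weights are (Cout x Cin*k*k) matrices whose patch axis is ordered
// channel-major, then kernel column, then kernel row:
//   patch index = (cin * k + dc) * k + dr.
// The im2col buffer is laid out (H*W x Cin*k*k) so that every write run is
// contiguous and the cube memory (slice-major, column-major slices) maps
// directly onto gemm inputs/outputs without reshapes.  All convolutions use
// "same" zero padding (k odd); the 1x1 head is the k = 1 case.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// cols(r + c*H, (cin*k + dc)*k + dr) = x(r + dr - p, c + dc - p, cin), 0 off-frame
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  mat cols(H * W, C * k * k, fill::zeros);
  for (int cin = 0; cin < C; ++cin) {
    const double* xs = x.slice_memptr(cin);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        double* col = cols.colptr((cin * k + dc) * k + dr);
        const int r0 = std::max(0, p - dr), r1 = std::min(H, H + p - dr);
        if (r0 >= r1) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc - p;
          if (sc < 0 || sc >= W) continue;
          std::memcpy(col + c * H + r0, xs + sc * H + (r0 + dr - p),
                      (r1 - r0) * sizeof(double));
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int p = (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int cin = 0; cin < C; ++cin) {
    double* xs = x.slice_memptr(cin);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const double* col = cols.colptr((cin * k + dc) * k + dr);
        const int r0 = std::max(0, p - dr), r1 = std::min(H, H + p - dr);
        if (r0 >= r1) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc - p;
          if (sc < 0 || sc >= W) continue;
          double* dst = xs + sc * H + (r0 + dr - p);
          const double* s = col + c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += s[r];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fw(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, const bool act,
                       const double slope) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int k = (int)std::lround(std::sqrt((double)w.n_cols / Cin));
  const int Cout = w.n_rows;
  cube y(H, W, Cout);
  mat ym(y.memptr(), H * W, Cout, false, true);  // alias the cube memory
  ym = im2col(x, k) * w.t();
  ym.each_row() += b.t();
  if (act) {
    double* p = y.memptr();
    const size_t n = y.n_elem;
    for (size_t i = 0; i < n; ++i)
      if (p[i] < 0) p[i] *= slope;
  }
  return y;
}

// gy is the gradient w.r.t. the post-activation output; y is that output
// (leaky ReLU is sign-preserving, so y > 0 identifies the positive branch).
// [[Rcpp::export]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& w,
                       const arma::cube& y, const arma::cube& gy,
                       const bool act, const double slope) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int k = (int)std::lround(std::sqrt((double)w.n_cols / Cin));
  const int Cout = w.n_rows;
  mat gm(H * W, Cout);
  {
    const double* gp = gy.memptr();
    double* dp = gm.memptr();
    const size_t n = gm.n_elem;
    if (act) {
      const double* yp = y.memptr();
      for (size_t i = 0; i < n; ++i) dp[i] = yp[i] > 0 ? gp[i] : slope * gp[i];
    } else {
      std::memcpy(dp, gp, n * sizeof(double));
    }
  }
  mat cols = im2col(x, k);
  mat gw = gm.t() * cols;           // Cout x Cin*k*k
  vec gb = sum(gm, 0).t();
  cube gx = col2im(gm * w, H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List cpp_pool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C);  // flat index (r + c*H) of the max within each slice
  for (int ch = 0; ch < C; ++ch) {
    const mat& sl = x.slice(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        int br = 2 * r, bc = 2 * c;
        double best = sl(br, bc);
        int bi = br + bc * H;
        // fixed scan order makes the argmax tie-break deterministic
        if (sl(br + 1, bc) > best) { best = sl(br + 1, bc); bi = br + 1 + bc * H; }
        if (sl(br, bc + 1) > best) { best = sl(br, bc + 1); bi = br + (bc + 1) * H; }
        if (sl(br + 1, bc + 1) > best) { best = sl(br + 1, bc + 1); bi = br + 1 + (bc + 1) * H; }
        y(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_pool_bw(const arma::cube& idx, const arma::cube& gy,
                       const int H, const int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* sl = gx.slice_memptr(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        sl[(size_t)idx(r, c, ch)] += gy(r, c, ch);
  }
  return gx;
}

// 2x2 stride-2 transposed convolution: output (2H, 2W, Cout); kernel blocks
// do not overlap.  Weight layout (Cout x Cin*4), patch index cin*4 + dc*2 + dr.
// [[Rcpp::export]]
arma::cube cpp_upconv_fw(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  const mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  cube y(2 * H, 2 * W, Cout);
  for (int dc = 0; dc < 2; ++dc) {
    for (int dr = 0; dr < 2; ++dr) {
      mat wd(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci) wd.row(ci) = w.col(ci * 4 + dc * 2 + dr).t();
      mat m = xm * wd;  // H*W x Cout
      for (int co = 0; co < Cout; ++co) {
        double* sl = y.slice_memptr(co);
        const double* src = m.colptr(co);
        const double bias = b(co);
        for (int c = 0; c < W; ++c) {
          double* dst = sl + (size_t)(2 * c + dc) * 2 * H + dr;
          const double* s = src + (size_t)c * H;
          for (int r = 0; r < H; ++r) dst[2 * r] = s[r] + bias;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv_bw(const arma::cube& x, const arma::mat& w,
                         const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  const mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  mat gxm(H * W, Cin, fill::zeros);
  mat gw(Cout, Cin * 4, fill::zeros);
  vec gb(Cout, fill::zeros);
  for (int dc = 0; dc < 2; ++dc) {
    for (int dr = 0; dr < 2; ++dr) {
      mat gym(H * W, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* sl = gy.slice_memptr(co);
        double* dst = gym.colptr(co);
        for (int c = 0; c < W; ++c) {
          const double* s = sl + (size_t)(2 * c + dc) * 2 * H + dr;
          double* d = dst + (size_t)c * H;
          for (int r = 0; r < H; ++r) d[r] = s[2 * r];
        }
      }
      mat wd(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci) wd.row(ci) = w.col(ci * 4 + dc * 2 + dr).t();
      gxm += gym * wd.t();
      mat gwd = gym.t() * xm;  // Cout x Cin
      for (int ci = 0; ci < Cin; ++ci) gw.col(ci * 4 + dc * 2 + dr) = gwd.col(ci);
      gb += sum(gym, 0).t();
    }
  }
  cube gx(gxm.memptr(), H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Inverse-mapped affine resampling about the image centre ((H+1)/2, (W+1)/2)
// in 1-based pixel coordinates.  For each destination pixel the source point
// is  A %*% (dest - centre) + t + centre;  bilinear = false gives
// nearest-neighbour with round-half-away-from-zero.  Out-of-frame source
// points take `fill`.  With A = I, t = 0 the source coordinates are exact
// integers, so the output is bit-identical to the input.
// [[Rcpp::export]]
arma::mat cpp_warp(const arma::mat& src, const arma::mat& A,
                   const arma::vec& t, const bool bilinear,
                   const double fill) {
  const int H = src.n_rows, W = src.n_cols;
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  mat out(H, W);
  auto at = [&](int rr, int cc2) {
    return (rr >= 1 && rr <= H && cc2 >= 1 && cc2 <= W) ? src(rr - 1, cc2 - 1)
                                                        : fill;
  };
  for (int c = 0; c < W; ++c) {
    const double dc = (c + 1) - cc;
    for (int r = 0; r < H; ++r) {
      const double dr = (r + 1) - cr;
      const double sr = A(0, 0) * dr + A(0, 1) * dc + t(0) + cr;
      const double sc = A(1, 0) * dr + A(1, 1) * dc + t(1) + cc;
      if (bilinear) {
        const double fr = std::floor(sr), fc = std::floor(sc);
        const double wr = sr - fr, wc = sc - fc;
        const int r0 = (int)fr, c0 = (int)fc;
        if (wr == 0 && wc == 0) {
          out(r, c) = at(r0, c0);
        } else {
          out(r, c) = (1 - wr) * (1 - wc) * at(r0, c0) +
                      wr * (1 - wc) * at(r0 + 1, c0) +
                      (1 - wr) * wc * at(r0, c0 + 1) +
                      wr * wc * at(r0 + 1, c0 + 1);
        }
      } else {
        const int rr = (int)std::round(sr), cc2 = (int)std::round(sc);
        out(r, c) = at(rr, cc2);
      }
    }
  }
  return out;
}

// Per-sample, per-channel (instance) normalisation over the H x W plane:
// y = gamma * (x - mean) / sqrt(var + eps) + beta.  Returns xhat and the
// inverse sd for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_inorm_fw(const arma::cube& x, const arma::vec& gamma,
                        const arma::vec& beta, const double eps) {
  const int C = x.n_slices;
  cube y(x.n_rows, x.n_cols, C), xhat(x.n_rows, x.n_cols, C);
  vec inv_sd(C);
  for (int ch = 0; ch < C; ++ch) {
    const mat& sl = x.slice(ch);
    const double mu = accu(sl) / sl.n_elem;
    const double v = accu(square(sl - mu)) / sl.n_elem;
    const double is = 1.0 / std::sqrt(v + eps);
    inv_sd(ch) = is;
    xhat.slice(ch) = (sl - mu) * is;
    y.slice(ch) = gamma(ch) * xhat.slice(ch) + beta(ch);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv_sd") = inv_sd);
}

// [[Rcpp::export]]
Rcpp::List cpp_inorm_bw(const arma::cube& xhat, const arma::vec& inv_sd,
                        const arma::vec& gamma, const arma::cube& gy) {
  const int C = gy.n_slices;
  cube gx(gy.n_rows, gy.n_cols, C);
  vec ggamma(C), gbeta(C);
  const double n = (double)gy.n_rows * gy.n_cols;
  for (int ch = 0; ch < C; ++ch) {
    const mat& g = gy.slice(ch);
    const mat& xh = xhat.slice(ch);
    const double sg = accu(g), sgx = accu(g % xh);
    ggamma(ch) = sgx;
    gbeta(ch) = sg;
    gx.slice(ch) = (gamma(ch) * inv_sd(ch)) * (g - sg / n - xh * (sgx / n));
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}

// [[Rcpp::export]]
arma::cube cpp_lrelu_fw(const arma::cube& x, const double slope) {
  cube y = x;
  double* p = y.memptr();
  for (size_t i = 0; i < y.n_elem; ++i)
    if (p[i] < 0) p[i] *= slope;
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_lrelu_bw(const arma::cube& y, const arma::cube& gy,
                        const double slope) {
  cube gx = gy;
  double* p = gx.memptr();
  const double* yp = y.memptr();
  for (size_t i = 0; i < gx.n_elem; ++i)
    if (yp[i] <= 0) p[i] *= slope;
  return gx;
}
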