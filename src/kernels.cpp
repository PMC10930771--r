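// Low-level numeric kernels: convolution (im2col + GEMM), pooling,
// bilinear and linearized multi-sampling, pyramid region reads and
// box downsampling. Images are R arrays dim (H, W, C), column-major,
// values in [0, 1]. All sampling uses the align-corners convention:
// normalized coordinate -1 maps to the first pixel center, +1 to the
// last.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int rdim(const NumericVector& x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// ---------------------------------------------------------------------------
// im2col for stride-1 same-size convolution with zero padding `pad`.
// Column order of the patch axis: (kh fastest, then kw, then cin), matching
// the column-major layout of an R weight array dim (kh, kw, cin, cout).
static void im2col_into(const double* x, int H, int W, int C,
                        int kh, int kw, int pad, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const int colidx = p + kh * (q + kw * c);
        double* dst = col.colptr(colidx);
        for (int j = 0; j < W; ++j) {
          const int sj = j + q - pad;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) dst[i + H * j] = 0.0;
          } else {
            const double* src = xc + (size_t)H * sj;
            for (int i = 0; i < H; ++i) {
              const int si = i + p - pad;
              dst[i + H * j] = (si < 0 || si >= H) ? 0.0 : src[si];
            }
          }
        }
      }
    }
  }
}

static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int pad) {
  arma::mat col(H * W, kh * kw * C);
  im2col_into(x, H, W, C, kh, kw, pad, col);
  return col;
}

// scatter-add transpose of im2col
static void col2im_add(const arma::mat& col, double* gx, int H, int W, int C,
                       int kh, int kw, int pad) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const int colidx = p + kh * (q + kw * c);
        const double* src = col.colptr(colidx);
        for (int j = 0; j < W; ++j) {
          const int sj = j + q - pad;
          if (sj < 0 || sj >= W) continue;
          double* dstc = gc + (size_t)H * sj;
          for (int i = 0; i < H; ++i) {
            const int si = i + p - pad;
            if (si >= 0 && si < H) dstc[si] += src[i + H * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  const int H = rdim(x, 0), W = rdim(x, 1), Cin = rdim(x, 2);
  const int kh = rdim(w, 0), kw = rdim(w, 1), Cout = rdim(w, 3);
  arma::mat col = im2col(x.begin(), H, W, Cin, kh, kw, pad);
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat out = col * wm;
  for (int o = 0; o < Cout; ++o) out.col(o) += b[o];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, Cout);
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int pad) {
  const int H = rdim(x, 0), W = rdim(x, 1), Cin = rdim(x, 2);
  const int kh = rdim(w, 0), kw = rdim(w, 1), Cout = rdim(w, 3);
  const int N = H * W;
  arma::mat col = im2col(x.begin(), H, W, Cin, kh, kw, pad);
  arma::mat gym(const_cast<double*>(gy.begin()), N, Cout, false, true);
  arma::mat gw = col.t() * gym;                    // (khkwCin x Cout)
  arma::rowvec gb = arma::sum(gym, 0);
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat gcol = gym * wm.t();                   // (N x khkwCin)
  NumericVector gx(x.size());
  col2im_add(gcol, gx.begin(), H, W, Cin, kh, kw, pad);
  gx.attr("dim") = x.attr("dim");
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---------------------------------------------------------------------------
// max pooling, kernel k x k, given stride and zero padding; returns argmax
// linear indices (1-based into the input array) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  const int H = rdim(x, 0), W = rdim(x, 1), C = rdim(x, 2);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector am((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const size_t xoff = (size_t)H * W * c;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300; long bidx = -1;
        for (int q = 0; q < k; ++q) {
          const int sj = j * stride + q - pad;
          if (sj < 0 || sj >= W) continue;
          for (int p = 0; p < k; ++p) {
            const int si = i * stride + p - pad;
            if (si < 0 || si >= H) continue;
            const double v = xp[xoff + (size_t)H * sj + si];
            if (v > best) { best = v; bidx = xoff + (size_t)H * sj + si; }
          }
        }
        const size_t oi = (size_t)Ho * Wo * c + (size_t)Ho * j + i;
        y[oi] = (bidx < 0) ? 0.0 : best;
        am[oi] = (int)(bidx + 1); // 0 => fully padded window
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2]);
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (argmax[i] > 0) gx[argmax[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// average pooling k x k, stride k (exact tiling assumed)
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int k) {
  const int H = rdim(x, 0), W = rdim(x, 1), C = rdim(x, 2);
  const int Ho = H / k, Wo = W / k;
  NumericVector y((size_t)Ho * Wo * C);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double s = 0;
        for (int q = 0; q < k; ++q)
          for (int p = 0; p < k; ++p)
            s += x[(size_t)H * W * c + (size_t)H * (j * k + q) + i * k + p];
        y[(size_t)Ho * Wo * c + (size_t)Ho * j + i] = s * inv;
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gy, int k, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = H / k, Wo = W / k;
  NumericVector gx((size_t)H * W * C);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gy[(size_t)Ho * Wo * c + (size_t)Ho * j + i] * inv;
        for (int q = 0; q < k; ++q)
          for (int p = 0; p < k; ++p)
            gx[(size_t)H * W * c + (size_t)H * (j * k + q) + i * k + p] += g;
      }
  gx.attr("dim") = xdim;
  return gx;
}

// ---------------------------------------------------------------------------
// bilinear lookup helpers (align-corners). Normalized x,y in [-1,1];
// positions outside the raster evaluate to 0 (black) with zero gradient
// beyond a one-pixel fade at the border.
struct BilTap { int idx[4]; double w[4]; double dwdx[4]; double dwdy[4]; int n; };

static inline void bil_taps(double xn, double yn, int H, int W, size_t coff,
                            BilTap& t) {
  // pixel-center index coordinates
  const double px = (xn + 1.0) * 0.5 * (W - 1);
  const double py = (yn + 1.0) * 0.5 * (H - 1);
  const double sx = 0.5 * (W - 1);  // d px / d xn
  const double sy = 0.5 * (H - 1);
  t.n = 0;
  const int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
  const double fx = px - x0, fy = py - y0;
  const int xs[2] = {x0, x0 + 1}, ys[2] = {y0, y0 + 1};
  const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy};
  const double dwx[2] = {-sx, sx}, dwy[2] = {-sy, sy};
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a) {
      const int xi = xs[a], yi = ys[b];
      if (xi < 0 || xi >= W || yi < 0 || yi >= H) continue;
      t.idx[t.n] = (int)(coff + (size_t)H * xi + yi);
      t.w[t.n] = wx[a] * wy[b];
      t.dwdx[t.n] = dwx[a] * wy[b];
      t.dwdy[t.n] = wx[a] * dwy[b];
      t.n++;
    }
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector img, NumericVector gx,
                               NumericVector gy) {
  const int H = rdim(img, 0), W = rdim(img, 1), C = rdim(img, 2);
  const int N = gx.size();
  const size_t plane = (size_t)H * W;
  NumericVector out((size_t)N * C);
  BilTap t;
  for (int n = 0; n < N; ++n) {
    bil_taps(gx[n], gy[n], H, W, 0, t);
    for (int c = 0; c < C; ++c) {
      double v = 0;
      for (int a = 0; a < t.n; ++a) v += t.w[a] * img[t.idx[a] + plane * c];
      out[(size_t)N * c + n] = v;
    }
  }
  out.attr("dim") = IntegerVector::create(N, C);
  return out;
}

// [[Rcpp::export]]
List cpp_bilinear_bwd(NumericVector img, NumericVector gx, NumericVector gy,
                      NumericVector gout) {
  const int H = rdim(img, 0), W = rdim(img, 1), C = rdim(img, 2);
  const int N = gx.size();
  const size_t plane = (size_t)H * W;
  NumericVector gimg(img.size()), ggx(N), ggy(N);
  BilTap t;
  for (int n = 0; n < N; ++n) {
    bil_taps(gx[n], gy[n], H, W, 0, t);
    double ax = 0, ay = 0;
    for (int c = 0; c < C; ++c) {
      const double g = gout[(size_t)N * c + n];
      for (int a = 0; a < t.n; ++a) {
        const size_t id = t.idx[a] + plane * c;
        gimg[id] += g * t.w[a];
        ax += g * t.dwdx[a] * img[id];
        ay += g * t.dwdy[a] * img[id];
      }
    }
    ggx[n] = ax; ggy[n] = ay;
  }
  gimg.attr("dim") = img.attr("dim");
  return List::create(_["gimg"] = gimg, _["ggx"] = ggx, _["ggy"] = ggy);
}

// ---------------------------------------------------------------------------
// Linearized multi-sampling. For each grid point, the image is evaluated at
// the point itself plus k jittered auxiliary points; a least-squares linear
// model v ~ b0 + b1*dx + b2*dy is fitted over the k+1 samples (offsets in
// normalized units). The forward value is the fitted intercept b0 and the
// coordinate gradients are the fitted slopes, which stay informative under
// heavy minification where plain bilinear gradients collapse. A degenerate
// fit (near-zero jitter) falls back to plain bilinear sampling.
struct LinFit {
  bool ok; double h[64]; // intercept hat-row over samples (k+1 <= 64)
  double b1w[64], b2w[64]; // slope hat-rows
};

static bool lin_hat(const double* ex, const double* ey, int m, LinFit& f) {
  // X is m x 3: columns (1, ex, ey); rows of (X'X)^{-1} X' via the
  // closed-form inverse of the symmetric 3x3 normal matrix
  double s1 = m, sx = 0, sy = 0, sxx = 0, sxy = 0, syy = 0;
  for (int j = 0; j < m; ++j) {
    sx += ex[j]; sy += ey[j];
    sxx += ex[j] * ex[j]; sxy += ex[j] * ey[j]; syy += ey[j] * ey[j];
  }
  const double c00 = sxx * syy - sxy * sxy;
  const double c01 = sy * sxy - sx * syy;
  const double c02 = sx * sxy - sy * sxx;
  const double det = s1 * c00 + sx * c01 + sy * c02;
  if (std::abs(det) < 1e-14) return false;
  const double id = 1.0 / det;
  const double a00 = c00 * id, a01 = c01 * id, a02 = c02 * id;
  const double a11 = (s1 * syy - sy * sy) * id;
  const double a12 = (sx * sy - s1 * sxy) * id;
  const double a22 = (s1 * sxx - sx * sx) * id;
  for (int j = 0; j < m; ++j) {
    f.h[j]   = a00 + a01 * ex[j] + a02 * ey[j];
    f.b1w[j] = a01 + a11 * ex[j] + a12 * ey[j];
    f.b2w[j] = a02 + a12 * ex[j] + a22 * ey[j];
  }
  return true;
}

// Deterministic counter-based jitter: splitmix64 keyed by (seed, point,
// sample, axis), mapped to uniform offsets in [-sqrt(3)*sd, sqrt(3)*sd]
// (matching the requested noise standard deviation). The same offsets are
// regenerated in the backward pass.
static inline double jitter(uint64_t seed, uint64_t n, uint64_t j,
                            uint64_t axis, double a) {
  uint64_t z = seed ^ (n * 0x9E3779B97F4A7C15ULL) ^
               (j * 0xBF58476D1CE4E5B9ULL) ^ (axis * 0x94D049BB133111EBULL);
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  const double u = (double)(z >> 11) / 9007199254740992.0; // [0, 1)
  return a * (2.0 * u - 1.0);
}

// both axes from a single hash (26 bits each)
static inline void jitter2(uint64_t seed, uint64_t n, uint64_t j, double a,
                           double* ex, double* ey) {
  uint64_t z = seed ^ (n * 0x9E3779B97F4A7C15ULL) ^
               (j * 0xBF58476D1CE4E5B9ULL);
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  const double u1 = (double)(z >> 38) / 67108864.0;          // [0, 1)
  const double u2 = (double)((z >> 12) & 0x3FFFFFFULL) / 67108864.0;
  *ex = a * (2.0 * u1 - 1.0);
  *ey = a * (2.0 * u2 - 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_linsample_fwd(NumericVector img, NumericVector gx,
                                NumericVector gy, int k, double noise_sd,
                                double seed) {
  const int H = rdim(img, 0), W = rdim(img, 1), C = rdim(img, 2);
  const int N = gx.size(), m = k + 1;
  const size_t plane = (size_t)H * W;
  const double amp = noise_sd * 1.7320508075688772;
  const uint64_t sd = (uint64_t)seed;
  NumericVector out((size_t)N * C);
  BilTap t; LinFit f;
  std::vector<double> exs(m), eys(m), b0(C);
  for (int n = 0; n < N; ++n) {
    exs[0] = 0; eys[0] = 0;
    for (int j = 1; j < m; ++j) jitter2(sd, n, j, amp, &exs[j], &eys[j]);
    const bool ok = (noise_sd > 0) && lin_hat(exs.data(), eys.data(), m, f);
    if (!ok) {
      bil_taps(gx[n], gy[n], H, W, 0, t);
      for (int c = 0; c < C; ++c) {
        double val = 0;
        for (int a = 0; a < t.n; ++a) val += t.w[a] * img[t.idx[a] + plane * c];
        out[(size_t)N * c + n] = val;
      }
      continue;
    }
    std::fill(b0.begin(), b0.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      bil_taps(gx[n] + exs[j], gy[n] + eys[j], H, W, 0, t);
      for (int c = 0; c < C; ++c) {
        double val = 0;
        for (int a = 0; a < t.n; ++a) val += t.w[a] * img[t.idx[a] + plane * c];
        b0[c] += f.h[j] * val;
      }
    }
    for (int c = 0; c < C; ++c) out[(size_t)N * c + n] = b0[c];
  }
  out.attr("dim") = IntegerVector::create(N, C);
  return out;
}

// [[Rcpp::export]]
List cpp_linsample_bwd(NumericVector img, NumericVector gx, NumericVector gy,
                       int k, double noise_sd, double seed,
                       NumericVector gout, bool need_gimg) {
  const int H = rdim(img, 0), W = rdim(img, 1), C = rdim(img, 2);
  const int N = gx.size(), m = k + 1;
  const size_t plane = (size_t)H * W;
  const double amp = noise_sd * 1.7320508075688772;
  const uint64_t sd = (uint64_t)seed;
  NumericVector gimg(need_gimg ? img.size() : 1), ggx(N), ggy(N);
  BilTap t; LinFit f;
  std::vector<double> exs(m), eys(m);
  for (int n = 0; n < N; ++n) {
    exs[0] = 0; eys[0] = 0;
    for (int j = 1; j < m; ++j) jitter2(sd, n, j, amp, &exs[j], &eys[j]);
    const bool ok = (noise_sd > 0) && lin_hat(exs.data(), eys.data(), m, f);
    double ax = 0, ay = 0;
    if (!ok) {
      bil_taps(gx[n], gy[n], H, W, 0, t);
      for (int c = 0; c < C; ++c) {
        const double g = gout[(size_t)N * c + n];
        for (int a = 0; a < t.n; ++a) {
          const size_t id = t.idx[a] + plane * c;
          if (need_gimg) gimg[id] += g * t.w[a];
          ax += g * t.dwdx[a] * img[id];
          ay += g * t.dwdy[a] * img[id];
        }
      }
      ggx[n] = ax; ggy[n] = ay;
      continue;
    }
    for (int j = 0; j < m; ++j) {
      bil_taps(gx[n] + exs[j], gy[n] + eys[j], H, W, 0, t);
      for (int c = 0; c < C; ++c) {
        const double g = gout[(size_t)N * c + n];
        double val = 0;
        if (need_gimg) {
          for (int a = 0; a < t.n; ++a) {
            const size_t id = t.idx[a] + plane * c;
            val += t.w[a] * img[id];
            gimg[id] += g * f.h[j] * t.w[a];
          }
        } else {
          for (int a = 0; a < t.n; ++a) val += t.w[a] * img[t.idx[a] + plane * c];
        }
        ax += g * f.b1w[j] * val;
        ay += g * f.b2w[j] * val;
      }
    }
    ggx[n] = ax; ggy[n] = ay;
  }
  if (need_gimg) gimg.attr("dim") = img.attr("dim");
  return List::create(_["gimg"] = gimg, _["ggx"] = ggx, _["ggy"] = ggy);
}

// quantize a [0,1] image to 8-bit raw bytes (round, clamp)
// [[Rcpp::export]]
RawVector cpp_to_raw(NumericVector img) {
  RawVector out(img.size());
  for (R_xlen_t i = 0; i < img.size(); ++i) {
    double v = std::nearbyint(img[i] * 255.0);
    out[i] = (Rbyte)(v < 0 ? 0 : (v > 255 ? 255 : v));
  }
  out.attr("dim") = img.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// Read a rectangle (x0,y0)-(x1,y1) in level-pixel units from an 8-bit level
// raster and bilinearly resize it to ch x cw, placed at offset (oy, ox)
// inside a black out_side x out_side canvas. Level pixel i covers [i, i+1).
// [[Rcpp::export]]
NumericVector cpp_read_region(RawVector lev, int H, int W,
                              double x0, double y0, double x1, double y1,
                              int cw, int ch, int out_side, int ox, int oy) {
  NumericVector out((size_t)out_side * out_side * 3);
  const double sx = (x1 - x0) / cw, sy = (y1 - y0) / ch;
  for (int c = 0; c < 3; ++c) {
    const size_t coff = (size_t)H * W * c;
    for (int j = 0; j < cw; ++j) {
      const double px = x0 + (j + 0.5) * sx - 0.5;
      const int xb = (int)std::floor(px);
      const double fx = px - xb;
      for (int i = 0; i < ch; ++i) {
        const double py = y0 + (i + 0.5) * sy - 0.5;
        const int yb = (int)std::floor(py);
        const double fy = py - yb;
        double v = 0;
        for (int b = 0; b < 2; ++b) {
          const int yy = yb + b;
          if (yy < 0 || yy >= H) continue;
          const double wy = b ? fy : 1.0 - fy;
          for (int a = 0; a < 2; ++a) {
            const int xx = xb + a;
            if (xx < 0 || xx >= W) continue;
            const double wx = a ? fx : 1.0 - fx;
            v += wy * wx * (double)lev[coff + (size_t)H * xx + yy];
          }
        }
        out[(size_t)out_side * out_side * c +
            (size_t)out_side * (ox + j) + (oy + i)] = v / 255.0;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(out_side, out_side, 3);
  return out;
}

// 2x box (area-mean) downsampling with ceil-sized output; edge cells
// average whatever pixels exist.
// [[Rcpp::export]]
NumericVector cpp_box_down2(NumericVector img) {
  const int H = rdim(img, 0), W = rdim(img, 1), C = rdim(img, 2);
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector out((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double s = 0; int cnt = 0;
        for (int q = 0; q < 2; ++q) {
          const int sj = 2 * j + q;
          if (sj >= W) continue;
          for (int p = 0; p < 2; ++p) {
            const int si = 2 * i + p;
            if (si >= H) continue;
            s += img[(size_t)H * W * c + (size_t)H * sj + si];
            cnt++;
          }
        }
        out[(size_t)Ho * Wo * c + (size_t)Ho * j + i] = s / cnt;
      }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// generic bilinear resize (pixel-area mapping), used by resize_pad and the
// synthetic texture generator
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int oh, int ow) {
  const int H = rdim(img, 0), W = rdim(img, 1), C = rdim(img, 2);
  NumericVector out((size_t)oh * ow * C);
  const double sx = (double)W / ow, sy = (double)H / oh;
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)H * W * c;
    for (int j = 0; j < ow; ++j) {
      double px = (j + 0.5) * sx - 0.5;
      if (px < 0) px = 0; if (px > W - 1) px = W - 1;
      const int xb = (int)std::floor(px);
      const int xt = std::min(xb + 1, W - 1);
      const double fx = px - xb;
      for (int i = 0; i < oh; ++i) {
        double py = (i + 0.5) * sy - 0.5;
        if (py < 0) py = 0; if (py > H - 1) py = H - 1;
        const int yb = (int)std::floor(py);
        const int yt = std::min(yb + 1, H - 1);
        const double fy = py - yb;
        const double v =
          (1 - fy) * ((1 - fx) * img[coff + (size_t)H * xb + yb] +
                      fx * img[coff + (size_t)H * xt + yb]) +
          fy * ((1 - fx) * img[coff + (size_t)H * xb + yt] +
                fx * img[coff + (size_t)H * xt + yt]);
        out[(size_t)oh * ow * c + (size_t)oh * j + i] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  return out;
}

// ---------------------------------------------------------------------------
// batch-norm over one image: statistics per channel across H*W
// [[Rcpp::export]]
NumericVector cpp_bn_fwd(NumericVector x, NumericVector mu, NumericVector istd,
                         NumericVector gamma, NumericVector beta) {
  const int H = rdim(x, 0), W = rdim(x, 1), C = rdim(x, 2);
  const size_t n = (size_t)H * W;
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    const double* xc = x.begin() + n * c;
    double* yc = y.begin() + n * c;
    for (size_t i = 0; i < n; ++i) yc[i] = (xc[i] - m) * is * g + b;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector mu, NumericVector istd,
                NumericVector gamma, NumericVector gy, bool training) {
  const int H = rdim(x, 0), W = rdim(x, 1), C = rdim(x, 2);
  const size_t n = (size_t)H * W;
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c];
    const double* xc = x.begin() + n * c;
    const double* gc = gy.begin() + n * c;
    double* oxc = gx.begin() + n * c;
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < n; ++i) {
      const double xh = (xc[i] - m) * is;
      sg += gc[i];
      sgx += gc[i] * xh;
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    if (training) {
      const double mg = sg / n, mgx = sgx / n;
      for (size_t i = 0; i < n; ++i) {
        const double xh = (xc[i] - m) * is;
        oxc[i] = (gc[i] - mg - xh * mgx) * g * is;
      }
    } else {
      for (size_t i = 0; i < n; ++i) oxc[i] = gc[i] * g * is;
    }
  }
  gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// grey filter on an (N, 3) sample matrix: rows whose channel spread is
// below tau (0-255 scale) are zeroed; returns the kept-row mask
// [[Rcpp::export]]
List cpp_grey_apply(NumericVector x, double tau) {
  const int N = rdim(x, 0);
  NumericVector y(x.size());
  LogicalVector keep(N);
  const double thr = (tau - 1e-9) / 255.0;
  const double* r = x.begin();
  const double* g = x.begin() + N;
  const double* b = x.begin() + 2 * (size_t)N;
  double* yr = y.begin(); double* yg = y.begin() + N;
  double* yb = y.begin() + 2 * (size_t)N;
  for (int i = 0; i < N; ++i) {
    const double mx = std::max(r[i], std::max(g[i], b[i]));
    const double mn = std::min(r[i], std::min(g[i], b[i]));
    const bool k = (mx - mn) >= thr;
    keep[i] = k;
    if (k) { yr[i] = r[i]; yg[i] = g[i]; yb[i] = b[i]; }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["keep"] = keep);
}

// backward of conv2d reusing the forward's im2col matrix
// [[Rcpp::export]]
List cpp_conv2d_bwd_col(NumericMatrix col, NumericVector w, NumericVector gy,
                        IntegerVector xdim, int pad) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int kh = rdim(w, 0), kw = rdim(w, 1), Cout = rdim(w, 3);
  const int N = H * W;
  arma::mat colm(const_cast<double*>(col.begin()), N, kh * kw * Cin, false, true);
  arma::mat gym(const_cast<double*>(gy.begin()), N, Cout, false, true);
  arma::mat gw = colm.t() * gym;
  arma::rowvec gb = arma::sum(gym, 0);
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat gcol = gym * wm.t();
  NumericVector gx((size_t)H * W * Cin);
  col2im_add(gcol, gx.begin(), H, W, Cin, kh, kw, pad);
  gx.attr("dim") = xdim;
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// forward returning both output and the im2col matrix for reuse
// [[Rcpp::export]]
List cpp_conv2d_fwd_col(NumericVector x, NumericVector w, NumericVector b,
                        int pad) {
  const int H = rdim(x, 0), W = rdim(x, 1), Cin = rdim(x, 2);
  const int kh = rdim(w, 0), kw = rdim(w, 1), Cout = rdim(w, 3);
  NumericMatrix colR(H * W, kh * kw * Cin);
  arma::mat col(colR.begin(), H * W, kh * kw * Cin, false, true);
  im2col_into(x.begin(), H, W, Cin, kh, kw, pad, col);
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat out = col * wm;
  for (int o = 0; o < Cout; ++o) out.col(o) += b[o];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, Cout);
  return List::create(_["y"] = res, _["col"] = colR);
}

// ---------------------------------------------------------------------------
// Single-pass renderer for the synthetic slide. Coarse noise grids are
// drawn in R (so all randomness stays on R's RNG) and bilinearly upsampled
// here. Column-major (S, S, 3) output.
static inline double grid_at(const double* g, int n, double u, double v) {
  // u, v in [0, 1); grid of n x n cells, bilinear between cell centers
  double px = u * n - 0.5, py = v * n - 0.5;
  if (px < 0) px = 0; if (px > n - 1) px = n - 1;
  if (py < 0) py = 0; if (py > n - 1) py = n - 1;
  const int x0 = (int)px, y0 = (int)py;
  const int x1 = std::min(x0 + 1, n - 1), y1 = std::min(y0 + 1, n - 1);
  const double fx = px - x0, fy = py - y0;
  return (1 - fy) * ((1 - fx) * g[y0 + n * x0] + fx * g[y0 + n * x1]) +
         fy * ((1 - fx) * g[y1 + n * x0] + fx * g[y1 + n * x1]);
}

// [[Rcpp::export]]
NumericVector cpp_render_slide(int S, NumericMatrix bg_noise,
                               NumericMatrix blob_noise,
                               NumericMatrix tex_noise, double thr,
                               NumericVector base, NumericVector lesion_base,
                               double lx, double ly, double lr, int has_lesion,
                               NumericMatrix smudges, double tex_fine_amp,
                               double fine_seed, NumericVector speck,
                               double speck_thr) {
  NumericVector img((size_t)S * S * 3);
  const int nbg = bg_noise.nrow(), nbl = blob_noise.nrow(),
            ntx = tex_noise.nrow();
  const size_t plane = (size_t)S * S;
  const uint64_t fs = (uint64_t)fine_seed;
  for (int j = 0; j < S; ++j) {
    const double u = (j + 0.5) / S;
    for (int i = 0; i < S; ++i) {
      const double v = (i + 0.5) / S;
      const size_t off = (size_t)S * j + i;
      double r, g, b;
      const double field = -std::sqrt((u - 0.5) * (u - 0.5) +
                                      (v - 0.5) * (v - 0.5)) +
                           grid_at(blob_noise.begin(), nbl, u, v);
      if (field > thr) {
        const double tex = grid_at(tex_noise.begin(), ntx, u, v) +
                           jitter(fs, off, 1, 0, tex_fine_amp);
        r = base[0] * (1 + tex); g = base[1] * (1 + tex);
        b = base[2] * (1 + tex);
      } else {
        const double bgv = 0.96 + grid_at(bg_noise.begin(), nbg, u, v);
        r = bgv; g = bgv; b = bgv;
      }
      // grey smudges (channels exactly equal)
      for (int s = 0; s < smudges.nrow(); ++s) {
        const double dx = (j + 0.5) - smudges(s, 0);
        const double dy = (i + 0.5) - smudges(s, 1);
        const double rr = smudges(s, 2);
        if (dx * dx + dy * dy < rr * rr) { r = g = b = smudges(s, 3); }
      }
      img[off] = r; img[off + plane] = g; img[off + 2 * plane] = b;
    }
  }
  if (has_lesion) {
    const int x0 = std::max(0, (int)std::floor(lx - lr) - 1);
    const int x1 = std::min(S - 1, (int)std::ceil(lx + lr));
    const int y0 = std::max(0, (int)std::floor(ly - lr) - 1);
    const int y1 = std::min(S - 1, (int)std::ceil(ly + lr));
    int si = 0;
    const int ns = speck.size();
    for (int j = x0; j <= x1; ++j)
      for (int i = y0; i <= y1; ++i) {
        const double dx = (j + 0.5) - lx, dy = (i + 0.5) - ly;
        if (dx * dx + dy * dy < lr * lr) {
          const double f = (speck[si % ns] < speck_thr) ? 0.55 : 1.0;
          si++;
          const size_t off = (size_t)S * j + i;
          img[off] = lesion_base[0] * f;
          img[off + plane] = lesion_base[1] * f;
          img[off + 2 * plane] = lesion_base[2] * f;
        }
      }
  }
  img.attr("dim") = IntegerVector::create(S, S, 3);
  return img;
}
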