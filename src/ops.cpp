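#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim c(H, W, C, N), column-major.
// im2col column index m = ho + Ho*(wo + Wo*n); row index r = ki + kh*(kj + kw*c).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  const int M = Ho * Wo * N;
  NumericMatrix out(K, M);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int m = ho + Ho * (wo + Wo * n);
        double *col = po + (R_xlen_t)m * K;
        for (int c = 0; c < C; ++c) {
          const double *plane = px + (R_xlen_t)(c + C * n) * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = wo * stride - pad + kj;
            for (int ki = 0; ki < kh; ++ki) {
              const int h = ho * stride - pad + ki;
              const int r = ki + kh * (kj + kw * c);
              col[r] = (h >= 0 && h < H && w >= 0 && w < W)
                           ? plane[h + (R_xlen_t)H * w]
                           : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((R_xlen_t)H * W * C * N);
  double *po = out.begin();
  const double *pc = cols.begin();
  const int K = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int m = ho + Ho * (wo + Wo * n);
        const double *col = pc + (R_xlen_t)m * K;
        for (int c = 0; c < C; ++c) {
          double *plane = po + (R_xlen_t)(c + C * n) * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              plane[h + (R_xlen_t)H * w] += col[ki + kh * (kj + kw * c)];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// 2x2 max pooling, stride 2. Returns list(out, idx) where idx holds the
// 1-based linear index (within the full input array) of each selected max.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t poff = (R_xlen_t)(c + C * n) * H * W;
      const R_xlen_t ooff = (R_xlen_t)(c + C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          R_xlen_t besti = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const R_xlen_t i = poff + (2 * ho + di) + (R_xlen_t)H * (2 * wo + dj);
              if (px[i] > best) { best = px[i]; besti = i; }
            }
          out[ooff + ho + (R_xlen_t)Ho * wo] = best;
          idx[ooff + ho + (R_xlen_t)Ho * wo] = (int)(besti + 1);
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector grad, IntegerVector idx,
                               int H, int W, int C, int N) {
  NumericVector out((R_xlen_t)H * W * C * N);
  for (R_xlen_t i = 0; i < grad.size(); ++i) out[idx[i] - 1] += grad[i];
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, int H, int W, int C, int N) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t xoff = (R_xlen_t)(c + C * n) * H * W;
      const R_xlen_t ooff = (R_xlen_t)(c + C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          po[ooff + ho + (R_xlen_t)Ho * wo] =
              px[xoff + ho / 2 + (R_xlen_t)H * (wo / 2)];
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector grad, int H, int W, int C, int N) {
  // H, W are the *input* (small) spatial dims; grad has dims 2H x 2W.
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)H * W * C * N);
  const double *pg = grad.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t goff = (R_xlen_t)(c + C * n) * Ho * Wo;
      const R_xlen_t ooff = (R_xlen_t)(c + C * n) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          po[ooff + ho / 2 + (R_xlen_t)H * (wo / 2)] +=
              pg[goff + ho + (R_xlen_t)Ho * wo];
    }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Bilinear warp of a single-channel image (H x W matrix). For each output
// pixel (row yo, col xo), source coords are
//   xs = a11*xo + a12*yo + b1,  ys = a21*xo + a22*yo + b2
// (x = column index, y = row index, both 0-based); out-of-bounds samples
// contribute the fill value.
// [[Rcpp::export]]
NumericMatrix affine_warp_cpp(NumericMatrix img, int outH, int outW,
                              double a11, double a12, double b1,
                              double a21, double a22, double b2,
                              double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(outH, outW);
  for (int xo = 0; xo < outW; ++xo) {
    for (int yo = 0; yo < outH; ++yo) {
      const double xs = a11 * xo + a12 * yo + b1;
      const double ys = a21 * xo + a22 * yo + b2;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      double v = 0.0;
      bool any = false;
      double acc = 0.0;
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          const double wgt = (di ? fy : 1 - fy) * (dj ? fx : 1 - fx);
          const int yy = y0 + di, xx = x0 + dj;
          if (yy >= 0 && yy < H && xx >= 0 && xx < W) {
            acc += wgt * img(yy, xx);
            any = true;
          } else {
            acc += wgt * fill;
          }
        }
      v = any ? acc : fill;
      out(yo, xo) = v;
    }
  }
  return out;
}

// Separable Gaussian blur with reflective edges; sigma in pixels.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(refl(y + i, H), x);
      tmp(y, x) = acc;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(y, refl(x + i, W));
      out(y, x) = acc;
    }
  return out;
}
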