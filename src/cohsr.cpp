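// Numerical kernels: 2-D convolution (im2col + GEMM) with explicit backward
// passes for network training, and bicubic resampling / rigid warping used by
// the registration stage. Tensors are R arrays in (H, W, C, N) layout
// (column-major); convolution weights are (k, k, Cin, Cout).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dim4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col in transposed layout: KT is (Ho*Wo) x (k*k*Ci), so each
// (kh, kw, ci) feature fills one column with contiguous pixel runs.
static void im2col_t(const double *x, int H, int W, int Ci,
                     arma::mat &KT, int k, int stride, int Ho, int Wo) {
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < Ci; ++ci) {
    const double *xc = x + (size_t)H * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double *col = KT.colptr(kh + k * kw + k * k * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kw - pad;
          double *dst = col + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double *xcol = xc + (size_t)H * wi;
          if (stride == 1) {
            // contiguous run, clipped at the vertical borders
            const int h0 = std::max(0, pad - kh);            // first valid ho
            const int h1 = std::min(Ho, H + pad - kh);       // one past last
            for (int ho = 0; ho < h0; ++ho) dst[ho] = 0.0;
            if (h1 > h0)
              std::memcpy(dst + h0, xcol + (h0 + kh - pad),
                          (size_t)(h1 - h0) * sizeof(double));
            for (int ho = h1; ho < Ho; ++ho) dst[ho] = 0.0;
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + kh - pad;
              dst[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride = 1) {
  int xd[4]; get_dim4(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (k, k, Cin, Cout)");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[3];
  if (wd[1] != k || wd[2] != Ci) stop("weight shape mismatch");
  const int pad = (k - 1) / 2;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;

  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)k * k * Ci, Co, false);
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat KT((size_t)Ho * Wo, (size_t)k * k * Ci);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, KT, k, stride, Ho, Wo);
    arma::mat Yn(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    Yn = KT * Wm;
    for (int co = 0; co < Co; ++co) Yn.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride = 1) {
  int xd[4]; get_dim4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[3];
  const int pad = (k - 1) / 2;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;

  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)k * k * Ci, Co, false);
  NumericVector dx((size_t)H * W * Ci * N);
  dx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  NumericVector dw((size_t)k * k * Ci * Co);
  dw.attr("dim") = wd;
  NumericVector db(Co);
  arma::mat dWm(dw.begin(), (size_t)k * k * Ci, Co, false, true);
  arma::mat KT((size_t)Ho * Wo, (size_t)k * k * Ci);

  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double *>(dy.begin()) + (size_t)Ho * Wo * Co * n,
                  (size_t)Ho * Wo, Co, false);
    im2col_t(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, KT, k, stride, Ho, Wo);
    dWm += KT.t() * dYn;
    for (int co = 0; co < Co; ++co) db[co] += arma::accu(dYn.col(co));
    arma::mat dKT = dYn * Wm.t(); // (Ho*Wo) x (k*k*Ci)
    // col2im scatter-add (contiguous column reads)
    double *dxn = dx.begin() + (size_t)H * W * Ci * n;
    for (int ci = 0; ci < Ci; ++ci) {
      double *dxc = dxn + (size_t)H * W * ci;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const double *col = dKT.colptr(kh + k * kw + k * k * ci);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            double *dxcol = dxc + (size_t)H * wi;
            const double *src = col + (size_t)Ho * wo;
            if (stride == 1) {
              const int h0 = std::max(0, pad - kh);
              const int h1 = std::min(Ho, H + pad - kh);
              for (int ho = h0; ho < h1; ++ho) dxcol[ho + kh - pad] += src[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + kh - pad;
                if (hi >= 0 && hi < H) dxcol[hi] += src[ho];
              }
            }
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Catmull-Rom (a = -0.5) cubic kernel
static inline double cubic_w(double t) {
  const double a = -0.5;
  double at = std::fabs(t);
  if (at <= 1.0) return (a + 2.0) * at * at * at - (a + 3.0) * at * at + 1.0;
  if (at < 2.0) return a * at * at * at - 5.0 * a * at * at + 8.0 * a * at - 4.0 * a;
  return 0.0;
}

static inline double sample_bicubic(const NumericMatrix &img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double acc = 0.0;
  for (int j = -1; j <= 2; ++j) {
    const int cc = std::min(std::max(c0 + j, 0), W - 1);
    const double wc = cubic_w(c - (c0 + j));
    if (wc == 0.0) continue;
    for (int i = -1; i <= 2; ++i) {
      const int rr = std::min(std::max(r0 + i, 0), H - 1);
      const double wr = cubic_w(r - (r0 + i));
      acc += wr * wc * img(rr, cc);
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix resize_bicubic(NumericMatrix img, double factor) {
  if (factor < 1) stop("factor must be >= 1");
  const int Ho = (int)std::lround(img.nrow() * factor);
  const int Wo = (int)std::lround(img.ncol() * factor);
  NumericMatrix out(Ho, Wo);
  // top-left mapping: source coordinate = output index / factor, so an
  // aligned decimation (taking every factor-th output pixel) is exact
  for (int c = 0; c < Wo; ++c) {
    const double sc = c / factor;
    for (int r = 0; r < Ho; ++r) out(r, c) = sample_bicubic(img, r / factor, sc);
  }
  return out;
}

// Rigid warp: out(p) = img(R_theta (p - ctr) + ctr + t), bicubic sampling,
// out-of-range samples set to `fill`.
// [[Rcpp::export]]
NumericMatrix warp_rigid(NumericMatrix img, double theta_deg, double dy,
                         double dx, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double yr = r - cr, xc = c - cc;
      const double sy = ct * yr - st * xc + cr + dy;
      const double sx = st * yr + ct * xc + cc + dx;
      if (sy < 0 || sy > H - 1 || sx < 0 || sx > W - 1) {
        out(r, c) = fill;
      } else {
        out(r, c) = sample_bicubic(img, sy, sx);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *px = x.begin(); double *py = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : slope * px[i];
  return y;
}

// [[Rcpp::export]]
NumericVector nn_lrelu_bwd(NumericVector pre, NumericVector dy, double slope) {
  NumericVector dx(pre.size());
  dx.attr("dim") = pre.attr("dim");
  const double *pp = pre.begin(), *pd = dy.begin(); double *px = dx.begin();
  const R_xlen_t n = pre.size();
  for (R_xlen_t i = 0; i < n; ++i) px[i] = pp[i] > 0 ? pd[i] : slope * pd[i];
  return dx;
}
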