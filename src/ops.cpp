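// Low-level numeric kernels for the detector: grouped/depthwise 2-D
// convolution (forward and backward via im2col + GEMM), fused batch-norm
// passes, SiLU, and stride-1 max pooling with argmax caching.
// Feature maps are R arrays with dim c(N, C, H, W); convolution weights
// dim c(k, k, cin/groups, cout). Same-padding with pad = (k - 1) / 2
// (odd kernels only), so the output spatial size is ceil(H / stride).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int H, int k, int s) {
  int pad = (k - 1) / 2;
  return (H + 2 * pad - k) / s + 1;
}

// Gather image n from x [N,C,H,W] into contiguous slab [C,H,W] (c fastest? no:
// slab index c + C*(h + H*w), i.e. channel-fastest within each pixel column).
// Wait: we keep the R layout order (n,c,h,w) minus n, so slab[c + C*(h+H*w)].
static void gather_image(const double* x, int n, int N, int C, int H, int W,
                         double* slab) {
  size_t M = (size_t)C * H * W;
  if (N == 1) { std::memcpy(slab, x, M * sizeof(double)); return; }
  for (size_t i = 0; i < M; ++i) slab[i] = x[n + N * i];
}

static void scatter_image_add(double* y, int n, int N, size_t M, const double* slab) {
  if (N == 1) { std::memcpy(y, slab, M * sizeof(double)); return; }
  for (size_t i = 0; i < M; ++i) y[n + N * i] = slab[i];
}

// im2col from a contiguous [C,H,W] slab for channel group [c0, c0+cg).
// col is (cg*k*k) x (Ho*Wo), row r = ci + cg*(kh + k*kw), col j = ho + Ho*wo.
static void im2col_slab(const double* slab, int C, int H, int W,
                        int c0, int cg, int k, int s, arma::mat& col) {
  int pad = (k - 1) / 2;
  int Ho = out_dim(H, k, s), Wo = out_dim(W, k, s);
  double* cp = col.memptr();
  int nr = cg * k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* colj = cp + (size_t)nr * (ho + (size_t)Ho * wo);
      for (int kw = 0; kw < k; ++kw) {
        int iw = wo * s - pad + kw;
        for (int kh = 0; kh < k; ++kh) {
          int ih = ho * s - pad + kh;
          double* dst = colj + cg * (kh + k * kw);
          if (iw < 0 || iw >= W || ih < 0 || ih >= H) {
            std::memset(dst, 0, cg * sizeof(double));
          } else {
            std::memcpy(dst, slab + c0 + (size_t)C * (ih + (size_t)H * iw),
                        cg * sizeof(double));
          }
        }
      }
    }
  }
}

static void col2im_slab_add(double* slab, int C, int H, int W,
                            int c0, int cg, int k, int s, const arma::mat& col) {
  int pad = (k - 1) / 2;
  int Ho = out_dim(H, k, s), Wo = out_dim(W, k, s);
  const double* cp = col.memptr();
  int nr = cg * k * k;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const double* colj = cp + (size_t)nr * (ho + (size_t)Ho * wo);
      for (int kw = 0; kw < k; ++kw) {
        int iw = wo * s - pad + kw;
        if (iw < 0 || iw >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          int ih = ho * s - pad + kh;
          if (ih < 0 || ih >= H) continue;
          double* dst = slab + c0 + (size_t)C * (ih + (size_t)H * iw);
          const double* src = colj + cg * (kh + k * kw);
          for (int ci = 0; ci < cg; ++ci) dst[ci] += src[ci];
        }
      }
    }
}

// Pack weights of group g into a (cog x cg*k*k) matrix matching im2col rows.
static void pack_weights(const double* w, int k, int cg, int cog, int g,
                         arma::mat& Wm) {
  for (int oc = 0; oc < cog; ++oc)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int ci = 0; ci < cg; ++ci)
          Wm(oc, ci + cg * (kh + k * kw)) =
            w[kh + k * (kw + k * (ci + (size_t)cg * ((size_t)g * cog + oc)))];
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                        int stride, int groups) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cg = wd[2], cout = wd[3];
  if (C != cg * groups) stop("channel/group mismatch");
  int cog = cout / groups;
  int Ho = out_dim(H, k, stride), Wo = out_dim(W, k, stride);
  size_t HWo = (size_t)Ho * Wo;
  NumericVector y((size_t)N * cout * HWo);
  y.attr("dim") = IntegerVector::create(N, cout, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();

  std::vector<double> slab((size_t)C * H * W);
  std::vector<double> oslab((size_t)cout * HWo);
  std::vector<arma::mat> Wms(groups);
  for (int g = 0; g < groups; ++g) {
    Wms[g].set_size(cog, cg * k * k);
    pack_weights(w.begin(), k, cg, cog, g, Wms[g]);
  }
  arma::mat col;
  bool fast11 = (k == 1 && stride == 1 && groups == 1);
  if (!fast11) col.set_size(cg * k * k, HWo);

  for (int n = 0; n < N; ++n) {
    const double* src = xp;
    if (N == 1) src = xp; else { gather_image(xp, n, N, C, H, W, slab.data()); src = slab.data(); }
    // output as (cout x HWo) matrix: oslab[c + cout*j]
    if (fast11) {
      arma::mat X(const_cast<double*>(src), C, HWo, false, true);
      arma::mat Y(oslab.data(), cout, HWo, false, true);
      Y = Wms[0] * X;
    } else {
      arma::mat Y(oslab.data(), cout, HWo, false, true);
      for (int g = 0; g < groups; ++g) {
        im2col_slab(src, C, H, W, g * cg, cg, k, stride, col);
        Y.rows(g * cog, (g + 1) * cog - 1) = Wms[g] * col;
      }
    }
    if (bias.isNotNull()) {
      NumericVector bv(bias);
      for (size_t j = 0; j < HWo; ++j) {
        double* oj = oslab.data() + (size_t)cout * j;
        for (int c = 0; c < cout; ++c) oj[c] += bv[c];
      }
    }
    scatter_image_add(yp + (N == 1 ? 0 : 0), n, N, (size_t)cout * HWo, oslab.data());
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int groups, bool need_dx, bool need_db) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cg = wd[2], cout = wd[3];
  int cog = cout / groups;
  int Ho = out_dim(H, k, stride), Wo = out_dim(W, k, stride);
  size_t HWo = (size_t)Ho * Wo;
  NumericVector dw((size_t)k * k * cg * cout);
  dw.attr("dim") = IntegerVector::create(k, k, cg, cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)N * C * H * W);
    dx.attr("dim") = IntegerVector::create(N, C, H, W);
  }
  NumericVector db(cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();

  std::vector<double> slab((size_t)C * H * W), dslab;
  std::vector<double> dyslab((size_t)cout * HWo);
  if (need_dx) dslab.resize((size_t)C * H * W);
  std::vector<arma::mat> Wms(groups), dWms(groups);
  for (int g = 0; g < groups; ++g) {
    Wms[g].set_size(cog, cg * k * k);
    pack_weights(w.begin(), k, cg, cog, g, Wms[g]);
    dWms[g].zeros(cog, cg * k * k);
  }
  bool fast11 = (k == 1 && stride == 1 && groups == 1);
  arma::mat col;
  if (!fast11) col.set_size(cg * k * k, HWo);

  for (int n = 0; n < N; ++n) {
    const double* src;
    if (N == 1) src = xp;
    else { gather_image(xp, n, N, C, H, W, slab.data()); src = slab.data(); }
    gather_image(dyp, n, N, cout, Ho, Wo, dyslab.data());
    arma::mat dY(dyslab.data(), cout, HWo, false, true);
    if (need_db) {
      for (size_t j = 0; j < HWo; ++j) {
        const double* oj = dyslab.data() + (size_t)cout * j;
        for (int c = 0; c < cout; ++c) db[c] += oj[c];
      }
    }
    if (fast11) {
      arma::mat X(const_cast<double*>(src), C, HWo, false, true);
      dWms[0] += dY * X.t();
      if (need_dx) {
        arma::mat dX = Wms[0].t() * dY;
        if (N == 1) {
          double* dd = dx.begin();
          const double* sp = dX.memptr();
          for (size_t i = 0; i < (size_t)C * HWo; ++i) dd[i] += sp[i];
        } else {
          double* dd = dx.begin();
          const double* sp = dX.memptr();
          for (size_t i = 0; i < (size_t)C * HWo; ++i) dd[n + N * i] += sp[i];
        }
      }
    } else {
      if (need_dx) std::memset(dslab.data(), 0, dslab.size() * sizeof(double));
      for (int g = 0; g < groups; ++g) {
        im2col_slab(src, C, H, W, g * cg, cg, k, stride, col);
        arma::mat dYg = dY.rows(g * cog, (g + 1) * cog - 1);
        dWms[g] += dYg * col.t();
        if (need_dx) {
          arma::mat dcol = Wms[g].t() * dYg;
          col2im_slab_add(dslab.data(), C, H, W, g * cg, cg, k, stride, dcol);
        }
      }
      if (need_dx) {
        double* dd = dx.begin();
        if (N == 1) {
          for (size_t i = 0; i < dslab.size(); ++i) dd[i] += dslab[i];
        } else {
          for (size_t i = 0; i < dslab.size(); ++i) dd[n + N * i] += dslab[i];
        }
      }
    }
  }
  for (int g = 0; g < groups; ++g)
    for (int oc = 0; oc < cog; ++oc)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          for (int ci = 0; ci < cg; ++ci)
            dw[kh + k * (kw + k * (ci + (size_t)cg * ((size_t)g * cog + oc)))] =
              dWms[g](oc, ci + cg * (kh + k * kw));
  List out = List::create(_["dw"] = dw, _["db"] = db);
  if (need_dx) out["dx"] = dx;
  return out;
}

// Depthwise convolution (one k x k filter per channel).
// [[Rcpp::export(rng = false)]]
NumericVector dwconv_fw(NumericVector x, NumericVector w, int stride) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  int pad = (k - 1) / 2;
  int Ho = out_dim(H, k, stride), Wo = out_dim(W, k, stride);
  NumericVector y((size_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  // channel-fastest access within pixel: iterate output pixels, inner loop c.
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double* yout = yp + n + (size_t)N * (0 + (size_t)C * (ho + (size_t)Ho * wo));
        for (int c = 0; c < C; ++c) yout[(size_t)N * c] = 0.0;
        for (int kw = 0; kw < k; ++kw) {
          int iw = wo * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = ho * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const double* xin = xp + n + (size_t)N * (0 + (size_t)C * (ih + (size_t)H * iw));
            const double* wk = w.begin() + kh + k * kw;  // stride k*k per channel
            for (int c = 0; c < C; ++c)
              yout[(size_t)N * c] += wk[(size_t)k * k * c] * xin[(size_t)N * c];
          }
        }
      }
  return y;
}

// [[Rcpp::export(rng = false)]]
List dwconv_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  int pad = (k - 1) / 2;
  int Ho = out_dim(H, k, stride), Wo = out_dim(W, k, stride);
  NumericVector dw((size_t)k * k * C);
  dw.attr("dim") = IntegerVector::create(k, k, 1, C);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)N * C * H * W);
    dx.attr("dim") = IntegerVector::create(N, C, H, W);
  }
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double* gout = dyp + n + (size_t)N * (0 + (size_t)C * (ho + (size_t)Ho * wo));
        for (int kw = 0; kw < k; ++kw) {
          int iw = wo * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = ho * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const double* xin = xp + n + (size_t)N * (0 + (size_t)C * (ih + (size_t)H * iw));
            double* dxin = need_dx ?
              dx.begin() + n + (size_t)N * (0 + (size_t)C * (ih + (size_t)H * iw)) : nullptr;
            double* dwk = dw.begin() + kh + k * kw;
            const double* wk = w.begin() + kh + k * kw;
            for (int c = 0; c < C; ++c) {
              double gv = gout[(size_t)N * c];
              dwk[(size_t)k * k * c] += gv * xin[(size_t)N * c];
              if (need_dx) dxin[(size_t)N * c] += gv * wk[(size_t)k * k * c];
            }
          }
        }
      }
  List out = List::create(_["dw"] = dw);
  if (need_dx) out["dx"] = dx;
  return out;
}

// ---- fused batch-norm passes ----------------------------------------------

// Per-channel mean and biased variance in one pass over [N,C,H,W].
// [[Rcpp::export(rng = false)]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1];
  size_t HW = (size_t)xd[2] * xd[3];
  size_t M = (size_t)N * HW;
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  size_t NC = (size_t)N * C;
  for (size_t j = 0; j < HW; ++j) {
    const double* blk = xp + NC * j;
    for (int c = 0; c < C; ++c) {
      const double* p = blk + (size_t)N * c;
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) { s += p[n]; s2 += p[n] * p[n]; }
      mu[c] += s; var[c] += s2;
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= M;
    var[c] = var[c] / M - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = x * a[c] + b[c]
// [[Rcpp::export(rng = false)]]
NumericVector bn_apply(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1];
  size_t HW = (size_t)xd[2] * xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t NC = (size_t)N * C;
  for (size_t j = 0; j < HW; ++j)
    for (int c = 0; c < C; ++c) {
      const double* p = xp + NC * j + (size_t)N * c;
      double* q = yp + NC * j + (size_t)N * c;
      double ac = a[c], bc = b[c];
      for (int n = 0; n < N; ++n) q[n] = p[n] * ac + bc;
    }
  return y;
}

// Backward through train-mode BN given the raw conv output z, batch mean and
// inverse std. Returns dz, dgamma, dbeta.
// [[Rcpp::export(rng = false)]]
List bn_bw(NumericVector z, NumericVector dy, NumericVector mu,
           NumericVector istd, NumericVector gamma) {
  IntegerVector xd = z.attr("dim");
  int N = xd[0], C = xd[1];
  size_t HW = (size_t)xd[2] * xd[3];
  size_t M = (size_t)N * HW;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dz(z.size());
  dz.attr("dim") = xd;
  const double* zp = z.begin();
  const double* dp = dy.begin();
  size_t NC = (size_t)N * C;
  for (size_t j = 0; j < HW; ++j)
    for (int c = 0; c < C; ++c) {
      const double* pz = zp + NC * j + (size_t)N * c;
      const double* pd = dp + NC * j + (size_t)N * c;
      double m = mu[c], is = istd[c], s1 = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        s1 += pd[n];
        s2 += pd[n] * (pz[n] - m) * is;
      }
      dbeta[c] += s1; dgamma[c] += s2;
    }
  double* dzp = dz.begin();
  for (size_t j = 0; j < HW; ++j)
    for (int c = 0; c < C; ++c) {
      const double* pz = zp + NC * j + (size_t)N * c;
      const double* pd = dp + NC * j + (size_t)N * c;
      double* pq = dzp + NC * j + (size_t)N * c;
      double m = mu[c], is = istd[c], g = gamma[c];
      double a1 = dbeta[c] / M, a2 = dgamma[c] / M;
      for (int n = 0; n < N; ++n) {
        double xhat = (pz[n] - m) * is;
        pq[n] = g * is * (pd[n] - a1 - xhat * a2);
      }
    }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- activations -----------------------------------------------------------

// [[Rcpp::export(rng = false)]]
NumericVector silu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-xp[i]));
    yp[i] = xp[i] * s;
  }
  return y;
}

// gradient wrt pre-activation z, times upstream dy
// [[Rcpp::export(rng = false)]]
NumericVector silu_bw(NumericVector z, NumericVector dy) {
  NumericVector g(z.size());
  g.attr("dim") = z.attr("dim");
  const double* zp = z.begin();
  const double* dp = dy.begin();
  double* gp = g.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-zp[i]));
    gp[i] = dp[i] * s * (1.0 + zp[i] * (1.0 - s));
  }
  return g;
}

// ---- max pooling ------------------------------------------------------------

// stride-1 same-padding max pooling with argmax cache (1-based flat index).
// [[Rcpp::export(rng = false)]]
List maxpool_fw(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int pad = (k - 1) / 2;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  IntegerVector arg(x.size());
  const double* xp = x.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -INFINITY; size_t bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            int iw = w - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int ih = h - pad + kh;
              if (ih < 0 || ih >= H) continue;
              size_t xi = n + (size_t)N * (c + (size_t)C * (ih + (size_t)H * iw));
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          }
          size_t yi = n + (size_t)N * (c + (size_t)C * (h + (size_t)H * w));
          y[yi] = best;
          arg[yi] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector arg, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[arg[i] - 1] += dy[i];
  return dx;
}

// ---- fused conv + batch-norm + activation ----------------------------------
// act: 0 = none, 1 = silu, 2 = relu

static inline double act_apply(double v, int act) {
  if (act == 1) { double s = 1.0 / (1.0 + std::exp(-v)); return v * s; }
  if (act == 2) return v > 0 ? v : 0.0;
  return v;
}

// [[Rcpp::export(rng = false)]]
List conv_block_fw(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                   int stride, int groups, bool has_bn,
                   Nullable<NumericVector> gamma, Nullable<NumericVector> beta,
                   Nullable<NumericVector> rmean, Nullable<NumericVector> rvar,
                   bool training, int act, double eps) {
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  IntegerVector xd = x.attr("dim");
  int C = xd[1];
  bool depthwise = (groups == C && k > 1 && wd[2] == 1);
  NumericVector z = depthwise ? dwconv_fw(x, w, stride)
                              : conv2d_fw(x, w, bias, stride, groups);
  if (!has_bn) {
    if (act == 0) return List::create(_["y"] = z);
    NumericVector y(z.size()); y.attr("dim") = z.attr("dim");
    for (R_xlen_t i = 0; i < z.size(); ++i) y[i] = act_apply(z[i], act);
    return List::create(_["y"] = y, _["z"] = z);
  }
  IntegerVector zd = z.attr("dim");
  int N = zd[0], Cz = zd[1];
  size_t HW = (size_t)zd[2] * zd[3];
  size_t M = (size_t)N * HW;
  NumericVector mu(Cz), var(Cz);
  if (training) {
    List st = bn_stats(z);
    mu = st["mean"]; var = st["var"];
  } else {
    mu = NumericVector(rmean); var = NumericVector(rvar);
  }
  NumericVector ga(gamma), be(beta);
  NumericVector y(z.size()); y.attr("dim") = zd;
  std::vector<double> a(Cz), b(Cz);
  for (int c = 0; c < Cz; ++c) {
    double istd = 1.0 / std::sqrt(var[c] + eps);
    a[c] = ga[c] * istd;
    b[c] = be[c] - mu[c] * ga[c] * istd;
  }
  const double* zp = z.begin();
  double* yp = y.begin();
  size_t NC = (size_t)N * Cz;
  for (size_t j = 0; j < HW; ++j)
    for (int c = 0; c < Cz; ++c) {
      const double* p = zp + NC * j + (size_t)N * c;
      double* q = yp + NC * j + (size_t)N * c;
      for (int n = 0; n < N; ++n) q[n] = act_apply(p[n] * a[c] + b[c], act);
    }
  if (training)
    return List::create(_["y"] = y, _["z"] = z, _["mean"] = mu, _["var"] = var);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(rng = false)]]
List conv_block_bw(NumericVector x, NumericVector w, NumericVector dy,
                   Nullable<NumericVector> z_, int stride, int groups,
                   bool has_bn, Nullable<NumericVector> gamma_,
                   Nullable<NumericVector> beta_, Nullable<NumericVector> mu_,
                   Nullable<NumericVector> var_, int act, double eps,
                   bool need_dx, bool need_db) {
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  IntegerVector xd = x.attr("dim");
  int C = xd[1];
  bool depthwise = (groups == C && k > 1 && wd[2] == 1);
  NumericVector dz;
  NumericVector dgamma, dbeta;
  if (!has_bn) {
    if (act == 0) dz = dy;
    else {
      NumericVector z(z_);
      dz = NumericVector(dy.size()); dz.attr("dim") = dy.attr("dim");
      if (act == 1) {
        for (R_xlen_t i = 0; i < dy.size(); ++i) {
          double s = 1.0 / (1.0 + std::exp(-z[i]));
          dz[i] = dy[i] * s * (1.0 + z[i] * (1.0 - s));
        }
      } else {
        for (R_xlen_t i = 0; i < dy.size(); ++i) dz[i] = z[i] > 0 ? dy[i] : 0.0;
      }
    }
  } else {
    NumericVector z(z_), ga(gamma_), be(beta_), mu(mu_), var(var_);
    IntegerVector zd = z.attr("dim");
    int N = zd[0], Cz = zd[1];
    size_t HW = (size_t)zd[2] * zd[3];
    size_t M = (size_t)N * HW;
    size_t NC = (size_t)N * Cz;
    std::vector<double> a(Cz), b(Cz), istd(Cz);
    for (int c = 0; c < Cz; ++c) {
      istd[c] = 1.0 / std::sqrt(var[c] + eps);
      a[c] = ga[c] * istd[c];
      b[c] = be[c] - mu[c] * a[c];
    }
    dz = NumericVector(dy.size()); dz.attr("dim") = zd;
    dgamma = NumericVector(Cz); dbeta = NumericVector(Cz);
    const double* zp = z.begin();
    const double* dp = dy.begin();
    double* qp = dz.begin();
    // pass 1: activation grad into dz, accumulate channel sums
    for (size_t j = 0; j < HW; ++j)
      for (int c = 0; c < Cz; ++c) {
        const double* pz = zp + NC * j + (size_t)N * c;
        const double* pd = dp + NC * j + (size_t)N * c;
        double* pq = qp + NC * j + (size_t)N * c;
        double s1 = 0, s2 = 0;
        for (int n = 0; n < N; ++n) {
          double zbn = pz[n] * a[c] + b[c];
          double g = pd[n];
          if (act == 1) {
            double s = 1.0 / (1.0 + std::exp(-zbn));
            g *= s * (1.0 + zbn * (1.0 - s));
          } else if (act == 2) {
            g = zbn > 0 ? g : 0.0;
          }
          pq[n] = g;
          s1 += g;
          s2 += g * (pz[n] - mu[c]) * istd[c];
        }
        dbeta[c] += s1; dgamma[c] += s2;
      }
    // pass 2: BN input gradient in place
    for (size_t j = 0; j < HW; ++j)
      for (int c = 0; c < Cz; ++c) {
        const double* pz = zp + NC * j + (size_t)N * c;
        double* pq = qp + NC * j + (size_t)N * c;
        double m = mu[c], is = istd[c], g = ga[c];
        double a1 = dbeta[c] / M, a2 = dgamma[c] / M;
        for (int n = 0; n < N; ++n) {
          double xhat = (pz[n] - m) * is;
          pq[n] = g * is * (pq[n] - a1 - xhat * a2);
        }
      }
  }
  List r;
  if (depthwise) {
    r = dwconv_bw(x, w, dz, stride, need_dx);
    r["db"] = NumericVector(0);
  } else {
    r = conv2d_bw(x, w, dz, stride, groups, need_dx, need_db);
  }
  if (has_bn) { r["dgamma"] = dgamma; r["dbeta"] = dbeta; }
  return r;
}
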