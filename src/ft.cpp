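// Single-precision tensor engine used by the network graph. Feature maps
// live in C++ float buffers passed to R as external pointers; weights and
// small per-channel vectors stay in R doubles at the interface. Layout
// matches the R convention [N, C, H, W] column-major (n fastest).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct FT {
  int N, C, H, W;
  std::vector<float> v;
  FT(int n, int c, int h, int w) : N(n), C(c), H(h), W(w),
    v((size_t)n * c * h * w) {}
  size_t size() const { return v.size(); }
};

typedef XPtr<FT> FTP;

static FTP wrap_ft(FT* t) { return FTP(t, true); }

// [[Rcpp::export(rng = false)]]
SEXP ft_from_r(NumericVector x) {
  IntegerVector d = x.attr("dim");
  FT* t = new FT(d[0], d[1], d[2], d[3]);
  for (size_t i = 0; i < t->size(); ++i) t->v[i] = (float)x[i];
  return wrap_ft(t);
}

// [[Rcpp::export(rng = false)]]
NumericVector ft_to_r(SEXP xp) {
  FTP t(xp);
  NumericVector y(t->size());
  for (size_t i = 0; i < t->size(); ++i) y[i] = t->v[i];
  y.attr("dim") = IntegerVector::create(t->N, t->C, t->H, t->W);
  return y;
}

// [[Rcpp::export(rng = false)]]
IntegerVector ft_dim(SEXP xp) {
  FTP t(xp);
  return IntegerVector::create(t->N, t->C, t->H, t->W);
}

static inline int out_dim_f(int H, int k, int s) {
  int pad = (k - 1) / 2;
  return (H + 2 * pad - k) / s + 1;
}

static void gather_f(const float* x, int n, int N, size_t M, float* slab) {
  if (N == 1) { std::memcpy(slab, x, M * sizeof(float)); return; }
  for (size_t i = 0; i < M; ++i) slab[i] = x[n + (size_t)N * i];
}

static void scatter_f(float* y, int n, int N, size_t M, const float* slab) {
  if (N == 1) { std::memcpy(y, slab, M * sizeof(float)); return; }
  for (size_t i = 0; i < M; ++i) y[n + (size_t)N * i] = slab[i];
}

static void im2col_f(const float* slab, int C, int H, int W,
                     int c0, int cg, int k, int s, arma::fmat& col) {
  int pad = (k - 1) / 2;
  int Ho = out_dim_f(H, k, s), Wo = out_dim_f(W, k, s);
  float* cp = col.memptr();
  int nr = cg * k * k;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      float* colj = cp + (size_t)nr * (ho + (size_t)Ho * wo);
      for (int kw = 0; kw < k; ++kw) {
        int iw = wo * s - pad + kw;
        for (int kh = 0; kh < k; ++kh) {
          int ih = ho * s - pad + kh;
          float* dst = colj + cg * (kh + k * kw);
          if (iw < 0 || iw >= W || ih < 0 || ih >= H)
            std::memset(dst, 0, cg * sizeof(float));
          else
            std::memcpy(dst, slab + c0 + (size_t)C * (ih + (size_t)H * iw),
                        cg * sizeof(float));
        }
      }
    }
}

static void col2im_f(float* slab, int C, int H, int W,
                     int c0, int cg, int k, int s, const arma::fmat& col) {
  int pad = (k - 1) / 2;
  int Ho = out_dim_f(H, k, s), Wo = out_dim_f(W, k, s);
  const float* cp = col.memptr();
  int nr = cg * k * k;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const float* colj = cp + (size_t)nr * (ho + (size_t)Ho * wo);
      for (int kw = 0; kw < k; ++kw) {
        int iw = wo * s - pad + kw;
        if (iw < 0 || iw >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          int ih = ho * s - pad + kh;
          if (ih < 0 || ih >= H) continue;
          float* dst = slab + c0 + (size_t)C * (ih + (size_t)H * iw);
          const float* src = colj + cg * (kh + k * kw);
          for (int ci = 0; ci < cg; ++ci) dst[ci] += src[ci];
        }
      }
    }
}

static void pack_w_f(const double* w, int k, int cg, int cog, int g, arma::fmat& Wm) {
  for (int oc = 0; oc < cog; ++oc)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int ci = 0; ci < cg; ++ci)
          Wm(oc, ci + cg * (kh + k * kw)) =
            (float)w[kh + k * (kw + k * (ci + (size_t)cg * ((size_t)g * cog + oc)))];
}


// Specialized 3x3 depthwise convolution over contiguous [N*C] pixel blocks,
// with per-tap weights expanded over the batch dimension.
static void dw3_fw_f(const FT& x, const double* w, int s, FT& y) {
  int N = x.N, C = x.C, H = x.H, W = x.W;
  int Ho = y.H, Wo = y.W;
  size_t NC = (size_t)N * C;
  std::vector<float> wexp(9 * NC);
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh)
      for (int c = 0; c < C; ++c) {
        float wv = (float)w[kh + 3 * kw + 9 * c];
        for (int n = 0; n < N; ++n)
          wexp[(kh + 3 * kw) * NC + (size_t)N * c + n] = wv;
      }
  const float* xp = x.v.data();
  float* yp = y.v.data();
  std::memset(yp, 0, y.size() * sizeof(float));
  for (int kw = 0; kw < 3; ++kw) {
    int dwo = kw - 1;
    for (int kh = 0; kh < 3; ++kh) {
      int dho = kh - 1;
      const float* wt = wexp.data() + (kh + 3 * kw) * NC;
      int ho_lo = 0; while (ho_lo * s + dho < 0) ++ho_lo;
      int ho_hi = Ho; while (ho_hi > ho_lo && (ho_hi - 1) * s + dho >= H) --ho_hi;
      int wo_lo = 0; while (wo_lo * s + dwo < 0) ++wo_lo;
      int wo_hi = Wo; while (wo_hi > wo_lo && (wo_hi - 1) * s + dwo >= W) --wo_hi;
      for (int wo = wo_lo; wo < wo_hi; ++wo) {
        int iw = wo * s + dwo;
        const float* in_col = xp + NC * (size_t)H * iw;
        float* out_col = yp + NC * (size_t)Ho * wo;
        for (int ho = ho_lo; ho < ho_hi; ++ho) {
          const float* in_px = in_col + NC * (size_t)(ho * s + dho);
          float* out_px = out_col + NC * (size_t)ho;
          for (size_t i = 0; i < NC; ++i) out_px[i] += wt[i] * in_px[i];
        }
      }
    }
  }
}

static void dw3_bw_f(const FT& x, const double* w, const FT& dy, int s,
                     bool need_dx, NumericVector& dw, FT* dx) {
  int N = x.N, C = x.C, H = x.H, W = x.W;
  int Ho = dy.H, Wo = dy.W;
  size_t NC = (size_t)N * C;
  std::vector<float> wexp(9 * NC), dwacc(9 * NC, 0.0f);
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh)
      for (int c = 0; c < C; ++c) {
        float wv = (float)w[kh + 3 * kw + 9 * c];
        for (int n = 0; n < N; ++n)
          wexp[(kh + 3 * kw) * NC + (size_t)N * c + n] = wv;
      }
  const float* xp = x.v.data();
  const float* gp = dy.v.data();
  float* dxp = need_dx ? dx->v.data() : nullptr;
  for (int kw = 0; kw < 3; ++kw) {
    int dwo = kw - 1;
    for (int kh = 0; kh < 3; ++kh) {
      int dho = kh - 1;
      const float* wt = wexp.data() + (kh + 3 * kw) * NC;
      float* da = dwacc.data() + (kh + 3 * kw) * NC;
      int ho_lo = 0; while (ho_lo * s + dho < 0) ++ho_lo;
      int ho_hi = Ho; while (ho_hi > ho_lo && (ho_hi - 1) * s + dho >= H) --ho_hi;
      int wo_lo = 0; while (wo_lo * s + dwo < 0) ++wo_lo;
      int wo_hi = Wo; while (wo_hi > wo_lo && (wo_hi - 1) * s + dwo >= W) --wo_hi;
      for (int wo = wo_lo; wo < wo_hi; ++wo) {
        int iw = wo * s + dwo;
        const float* x_col = xp + NC * (size_t)H * iw;
        float* dx_col = need_dx ? dxp + NC * (size_t)H * iw : nullptr;
        const float* g_col = gp + NC * (size_t)Ho * wo;
        for (int ho = ho_lo; ho < ho_hi; ++ho) {
          const float* x_px = x_col + NC * (size_t)(ho * s + dho);
          const float* g_px = g_col + NC * (size_t)ho;
          if (need_dx) {
            float* dx_px = dx_col + NC * (size_t)(ho * s + dho);
            for (size_t i = 0; i < NC; ++i) {
              da[i] += g_px[i] * x_px[i];
              dx_px[i] += g_px[i] * wt[i];
            }
          } else {
            for (size_t i = 0; i < NC; ++i) da[i] += g_px[i] * x_px[i];
          }
        }
      }
    }
  }
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh)
      for (int c = 0; c < C; ++c) {
        double acc = 0;
        const float* da = dwacc.data() + (kh + 3 * kw) * NC + (size_t)N * c;
        for (int n = 0; n < N; ++n) acc += da[n];
        dw[kh + 3 * kw + 9 * c] = acc;
      }
}

// depthwise forward: one filter per channel, weights double [k,k,1,C]
static void dw_fw_f(const FT& x, const double* w, int k, int s, FT& y) {
  int N = x.N, C = x.C, H = x.H, W = x.W;
  int pad = (k - 1) / 2;
  int Ho = y.H, Wo = y.W;
  std::vector<float> wf((size_t)k * k * C);
  for (size_t i = 0; i < wf.size(); ++i) wf[i] = (float)w[i];
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        float* yout = y.v.data() + n + (size_t)N * ((size_t)C * (ho + (size_t)Ho * wo));
        for (int c = 0; c < C; ++c) yout[(size_t)N * c] = 0.0f;
        for (int kw = 0; kw < k; ++kw) {
          int iw = wo * s - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = ho * s - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const float* xin = x.v.data() + n + (size_t)N * ((size_t)C * (ih + (size_t)H * iw));
            const float* wk = wf.data() + kh + k * kw;
            for (int c = 0; c < C; ++c)
              yout[(size_t)N * c] += wk[(size_t)k * k * c] * xin[(size_t)N * c];
          }
        }
      }
}

static void dw_bw_f(const FT& x, const double* w, const FT& dy, int k, int s,
                    bool need_dx, NumericVector& dw, FT* dx) {
  int N = x.N, C = x.C, H = x.H, W = x.W;
  int pad = (k - 1) / 2;
  int Ho = dy.H, Wo = dy.W;
  std::vector<float> wf((size_t)k * k * C);
  for (size_t i = 0; i < wf.size(); ++i) wf[i] = (float)w[i];
  std::vector<double> dwa((size_t)k * k * C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const float* gout = dy.v.data() + n + (size_t)N * ((size_t)C * (ho + (size_t)Ho * wo));
        for (int kw = 0; kw < k; ++kw) {
          int iw = wo * s - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = ho * s - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const float* xin = x.v.data() + n + (size_t)N * ((size_t)C * (ih + (size_t)H * iw));
            float* dxin = need_dx ?
              dx->v.data() + n + (size_t)N * ((size_t)C * (ih + (size_t)H * iw)) : nullptr;
            double* dwk = dwa.data() + kh + k * kw;
            const float* wk = wf.data() + kh + k * kw;
            for (int c = 0; c < C; ++c) {
              float gv = gout[(size_t)N * c];
              dwk[(size_t)k * k * c] += (double)gv * xin[(size_t)N * c];
              if (need_dx) dxin[(size_t)N * c] += gv * wk[(size_t)k * k * c];
            }
          }
        }
      }
  for (size_t i = 0; i < dwa.size(); ++i) dw[i] = dwa[i];
}

// Fast float exp: 2^t split into integer/fraction, degree-6 polynomial for
// the fractional part. Relative accuracy ~1e-7, adequate for float math and
// ~4x faster than libm expf; avoids non-vectorizable libm calls.
static inline float fast_expf(float x) {
  if (x > 87.0f) x = 87.0f;
  if (x < -87.0f) x = -87.0f;
  float t = x * 1.44269504088896341f;
  float fi = std::floor(t);
  float f = t - fi;
  float p = 1.0f + f * (0.693147180559945f + f * (0.240226506959101f +
            f * (0.0555041086648216f + f * (0.00961812910762848f +
            f * (0.00133335581464284f + f * 0.000154353139101751f)))));
  union { uint32_t u; float fl; } sc;
  sc.u = (uint32_t)((int)fi + 127) << 23;
  return p * sc.fl;
}

static inline float sigm_f(float v) { return 1.0f / (1.0f + fast_expf(-v)); }

static inline float act_f(float v, int act) {
  if (act == 1) return v * sigm_f(v);
  if (act == 2) return v > 0 ? v : 0.0f;
  return v;
}

// Fused convolution + batch norm + activation, forward.
// [[Rcpp::export(rng = false)]]
List ft_conv_block_fw(SEXP xp, NumericVector w, Nullable<NumericVector> bias,
                      int stride, int groups, bool has_bn,
                      Nullable<NumericVector> gamma, Nullable<NumericVector> beta,
                      Nullable<NumericVector> rmean, Nullable<NumericVector> rvar,
                      bool training, int act, double eps) {
  FTP x(xp);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cg = wd[2], cout = wd[3];
  int N = x->N, C = x->C, H = x->H, W = x->W;
  bool depthwise = (groups == C && k > 1 && cg == 1);
  int Ho = out_dim_f(H, k, stride), Wo = out_dim_f(W, k, stride);
  size_t HWo = (size_t)Ho * Wo;
  FT* z = new FT(N, cout, Ho, Wo);
  if (depthwise) {
    if (k == 3) dw3_fw_f(*x, w.begin(), stride, *z);
    else dw_fw_f(*x, w.begin(), k, stride, *z);
  } else {
    int cog = cout / groups;
    std::vector<arma::fmat> Wms(groups);
    for (int g = 0; g < groups; ++g) {
      Wms[g].set_size(cog, cg * k * k);
      pack_w_f(w.begin(), k, cg, cog, g, Wms[g]);
    }
    bool fast11 = (k == 1 && stride == 1 && groups == 1);
    arma::fmat col;
    if (!fast11) col.set_size(cg * k * k, HWo);
    std::vector<float> slab, oslab;
    if (N > 1) { slab.resize((size_t)C * H * W); oslab.resize((size_t)cout * HWo); }
    for (int n = 0; n < N; ++n) {
      const float* src = x->v.data();
      if (N > 1) { gather_f(x->v.data(), n, N, (size_t)C * H * W, slab.data()); src = slab.data(); }
      float* dst = (N == 1) ? z->v.data() : oslab.data();
      arma::fmat Y(dst, cout, HWo, false, true);
      if (fast11) {
        arma::fmat X(const_cast<float*>(src), C, HWo, false, true);
        Y = Wms[0] * X;
      } else {
        for (int g = 0; g < groups; ++g) {
          int c0 = g * (C / groups);
          im2col_f(src, C, H, W, c0, cg, k, stride, col);
          Y.rows(g * (cout / groups), (g + 1) * (cout / groups) - 1) = Wms[g] * col;
        }
      }
      if (bias.isNotNull()) {
        NumericVector bv(bias);
        for (size_t j = 0; j < HWo; ++j) {
          float* oj = dst + (size_t)cout * j;
          for (int c = 0; c < cout; ++c) oj[c] += (float)bv[c];
        }
      }
      if (N > 1) scatter_f(z->v.data(), n, N, (size_t)cout * HWo, oslab.data());
    }
  }
  // batch norm + activation
  if (!has_bn) {
    if (act == 0) return List::create(_["y"] = wrap_ft(z));
    FT* y = new FT(N, cout, Ho, Wo);
    for (size_t i = 0; i < z->size(); ++i) y->v[i] = act_f(z->v[i], act);
    if (training) return List::create(_["y"] = wrap_ft(y), _["z"] = wrap_ft(z));
    delete z;
    return List::create(_["y"] = wrap_ft(y));
  }
  size_t M = (size_t)N * HWo;
  size_t NC = (size_t)N * cout;
  NumericVector mu(cout), var(cout);
  if (training) {
    std::vector<double> s1(NC, 0.0), s2(NC, 0.0);
    for (size_t j = 0; j < HWo; ++j) {
      const float* p = z->v.data() + NC * j;
      for (size_t i = 0; i < NC; ++i) {
        double v = p[i];
        s1[i] += v; s2[i] += v * v;
      }
    }
    for (int c = 0; c < cout; ++c) {
      double a = 0, b = 0;
      for (int n = 0; n < N; ++n) { a += s1[(size_t)N * c + n]; b += s2[(size_t)N * c + n]; }
      mu[c] = a / M;
      var[c] = std::max(0.0, b / M - mu[c] * mu[c]);
    }
  } else {
    mu = NumericVector(rmean); var = NumericVector(rvar);
  }
  NumericVector ga(gamma), be(beta);
  std::vector<float> af(NC), bf(NC);
  for (int c = 0; c < cout; ++c) {
    double istd = 1.0 / std::sqrt(var[c] + eps);
    float ac = (float)(ga[c] * istd);
    float bc = (float)(be[c] - mu[c] * ga[c] * istd);
    for (int n = 0; n < N; ++n) { af[(size_t)N * c + n] = ac; bf[(size_t)N * c + n] = bc; }
  }
  FT* y = new FT(N, cout, Ho, Wo);
  if (act == 1) {
    for (size_t j = 0; j < HWo; ++j) {
      const float* p = z->v.data() + NC * j;
      float* q = y->v.data() + NC * j;
      for (size_t i = 0; i < NC; ++i) {
        float v = p[i] * af[i] + bf[i];
        q[i] = v * sigm_f(v);
      }
    }
  } else if (act == 2) {
    for (size_t j = 0; j < HWo; ++j) {
      const float* p = z->v.data() + NC * j;
      float* q = y->v.data() + NC * j;
      for (size_t i = 0; i < NC; ++i) {
        float v = p[i] * af[i] + bf[i];
        q[i] = v > 0 ? v : 0.0f;
      }
    }
  } else {
    for (size_t j = 0; j < HWo; ++j) {
      const float* p = z->v.data() + NC * j;
      float* q = y->v.data() + NC * j;
      for (size_t i = 0; i < NC; ++i) q[i] = p[i] * af[i] + bf[i];
    }
  }
  if (training)
    return List::create(_["y"] = wrap_ft(y), _["z"] = wrap_ft(z),
                        _["mean"] = mu, _["var"] = var);
  delete z;
  return List::create(_["y"] = wrap_ft(y));
}

// Fused backward: activation + BN gradient, then convolution backward.
// [[Rcpp::export(rng = false)]]
List ft_conv_block_bw(SEXP xp, NumericVector w, SEXP dyp, SEXP zp,
                      int stride, int groups, bool has_bn,
                      Nullable<NumericVector> gamma_, Nullable<NumericVector> beta_,
                      Nullable<NumericVector> mu_, Nullable<NumericVector> var_,
                      int act, double eps, bool need_dx, bool need_db) {
  FTP x(xp); FTP dy(dyp);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cg = wd[2], cout = wd[3];
  int N = x->N, C = x->C, H = x->H, W = x->W;
  bool depthwise = (groups == C && k > 1 && cg == 1);
  int Ho = dy->H, Wo = dy->W;
  size_t HWo = (size_t)Ho * Wo;
  size_t M = (size_t)N * HWo;
  size_t NC = (size_t)N * cout;
  NumericVector dgamma, dbeta;

  // gradient wrt conv output z
  FT dz(N, cout, Ho, Wo);
  if (!has_bn) {
    if (act == 0) {
      std::memcpy(dz.v.data(), dy->v.data(), dz.size() * sizeof(float));
    } else {
      FTP z(zp);
      for (size_t i = 0; i < dz.size(); ++i) {
        float zv = z->v[i], g = dy->v[i];
        if (act == 1) {
          float s = sigm_f(zv);
          g *= s * (1.0f + zv * (1.0f - s));
        } else if (zv <= 0) g = 0.0f;
        dz.v[i] = g;
      }
    }
  } else {
    FTP z(zp);
    NumericVector ga(gamma_), be(beta_), mu(mu_), var(var_);
    std::vector<float> af(NC), bf(NC), istdf(NC), muf(NC), gistd(NC);
    for (int c = 0; c < cout; ++c) {
      double istd = 1.0 / std::sqrt(var[c] + eps);
      float ac = (float)(ga[c] * istd);
      float bc = (float)(be[c] - mu[c] * ga[c] * istd);
      for (int n = 0; n < N; ++n) {
        size_t i = (size_t)N * c + n;
        af[i] = ac; bf[i] = bc;
        istdf[i] = (float)istd; muf[i] = (float)mu[c];
        gistd[i] = (float)(ga[c] * istd);
      }
    }
    dgamma = NumericVector(cout); dbeta = NumericVector(cout);
    std::vector<double> S1(NC, 0.0), S2(NC, 0.0);
    // pass 1: activation grad into dz, accumulate per-(n,c) sums
    for (size_t j = 0; j < HWo; ++j) {
      const float* pz = z->v.data() + NC * j;
      const float* pd = dy->v.data() + NC * j;
      float* pq = dz.v.data() + NC * j;
      if (act == 1) {
        for (size_t i = 0; i < NC; ++i) {
          float zbn = pz[i] * af[i] + bf[i];
          float s = sigm_f(zbn);
          float g = pd[i] * s * (1.0f + zbn * (1.0f - s));
          pq[i] = g;
          S1[i] += g;
          S2[i] += (double)g * (pz[i] - muf[i]) * istdf[i];
        }
      } else if (act == 2) {
        for (size_t i = 0; i < NC; ++i) {
          float zbn = pz[i] * af[i] + bf[i];
          float g = zbn > 0 ? pd[i] : 0.0f;
          pq[i] = g;
          S1[i] += g;
          S2[i] += (double)g * (pz[i] - muf[i]) * istdf[i];
        }
      } else {
        for (size_t i = 0; i < NC; ++i) {
          float g = pd[i];
          pq[i] = g;
          S1[i] += g;
          S2[i] += (double)g * (pz[i] - muf[i]) * istdf[i];
        }
      }
    }
    std::vector<float> a1f(NC), a2f(NC);
    for (int c = 0; c < cout; ++c) {
      double s1 = 0, s2 = 0;
      for (int n = 0; n < N; ++n) { s1 += S1[(size_t)N * c + n]; s2 += S2[(size_t)N * c + n]; }
      dbeta[c] = s1; dgamma[c] = s2;
      for (int n = 0; n < N; ++n) {
        a1f[(size_t)N * c + n] = (float)(s1 / M);
        a2f[(size_t)N * c + n] = (float)(s2 / M);
      }
    }
    // pass 2: BN input gradient in place
    for (size_t j = 0; j < HWo; ++j) {
      const float* pz = z->v.data() + NC * j;
      float* pq = dz.v.data() + NC * j;
      for (size_t i = 0; i < NC; ++i) {
        float xhat = (pz[i] - muf[i]) * istdf[i];
        pq[i] = gistd[i] * (pq[i] - a1f[i] - xhat * a2f[i]);
      }
    }
  }

  NumericVector dw((size_t)k * k * cg * cout);
  dw.attr("dim") = IntegerVector::create(k, k, cg, cout);
  NumericVector db(need_db ? cout : 0);
  FT* dx = need_dx ? new FT(N, C, H, W) : nullptr;

  if (depthwise) {
    if (k == 3) dw3_bw_f(*x, w.begin(), dz, stride, need_dx, dw, dx);
    else dw_bw_f(*x, w.begin(), dz, k, stride, need_dx, dw, dx);
  } else {
    int cog = cout / groups;
    std::vector<arma::fmat> Wms(groups), dWms(groups);
    for (int g = 0; g < groups; ++g) {
      Wms[g].set_size(cog, cg * k * k);
      pack_w_f(w.begin(), k, cg, cog, g, Wms[g]);
      dWms[g].zeros(cog, cg * k * k);
    }
    bool fast11 = (k == 1 && stride == 1 && groups == 1);
    arma::fmat col;
    if (!fast11) col.set_size(cg * k * k, HWo);
    std::vector<float> slab, dyslab, dxslab;
    if (N > 1) { slab.resize((size_t)C * H * W); dyslab.resize((size_t)cout * HWo); }
    if (need_dx && (N > 1 || !fast11)) dxslab.resize((size_t)C * H * W);
    for (int n = 0; n < N; ++n) {
      const float* src = x->v.data();
      float* dyd = dz.v.data();
      if (N > 1) {
        gather_f(x->v.data(), n, N, (size_t)C * H * W, slab.data());
        src = slab.data();
        gather_f(dz.v.data(), n, N, (size_t)cout * HWo, dyslab.data());
        dyd = dyslab.data();
      }
      arma::fmat dY(dyd, cout, HWo, false, true);
      if (need_db)
        for (size_t j = 0; j < HWo; ++j) {
          const float* oj = dyd + (size_t)cout * j;
          for (int c = 0; c < cout; ++c) db[c] += oj[c];
        }
      if (fast11) {
        arma::fmat X(const_cast<float*>(src), C, HWo, false, true);
        dWms[0] += dY * X.t();
        if (need_dx) {
          if (N == 1) {
            arma::fmat dX(dx->v.data(), C, HWo, false, true);
            dX = Wms[0].t() * dY;
          } else {
            arma::fmat dX = Wms[0].t() * dY;
            scatter_f(dx->v.data(), n, N, (size_t)C * HWo, dX.memptr());
          }
        }
      } else {
        if (need_dx) std::memset(dxslab.data(), 0, dxslab.size() * sizeof(float));
        for (int g = 0; g < groups; ++g) {
          int c0 = g * (C / groups);
          im2col_f(src, C, H, W, c0, cg, k, stride, col);
          arma::fmat dYg = dY.rows(g * cog, (g + 1) * cog - 1);
          dWms[g] += dYg * col.t();
          if (need_dx) {
            arma::fmat dcol = Wms[g].t() * dYg;
            col2im_f(dxslab.data(), C, H, W, c0, cg, k, stride, dcol);
          }
        }
        if (need_dx) scatter_f(dx->v.data(), n, N, (size_t)C * H * W, dxslab.data());
      }
    }
    for (int g = 0; g < groups; ++g)
      for (int oc = 0; oc < cog; ++oc)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            for (int ci = 0; ci < cg; ++ci)
              dw[kh + k * (kw + k * (ci + (size_t)cg * ((size_t)g * cog + oc)))] =
                dWms[g](oc, ci + cg * (kh + k * kw));
  }
  List out = List::create(_["dw"] = dw);
  if (need_db) out["db"] = db;
  if (has_bn) { out["dgamma"] = dgamma; out["dbeta"] = dbeta; }
  if (need_dx) out["dx"] = wrap_ft(dx);
  return out;
}

// ---- elementwise / structural ops -----------------------------------------

// [[Rcpp::export(rng = false)]]
SEXP ft_add(SEXP ap, SEXP bp) {
  FTP a(ap), b(bp);
  FT* y = new FT(a->N, a->C, a->H, a->W);
  for (size_t i = 0; i < y->size(); ++i) y->v[i] = a->v[i] + b->v[i];
  return wrap_ft(y);
}

// [[Rcpp::export(rng = false)]]
SEXP ft_concat(List xs) {
  std::vector<FTP> ts;
  int Ctot = 0;
  for (int i = 0; i < xs.size(); ++i) {
    FTP t(as<SEXP>(xs[i]));
    ts.push_back(t);
    Ctot += t->C;
  }
  int N = ts[0]->N, H = ts[0]->H, W = ts[0]->W;
  FT* y = new FT(N, Ctot, H, W);
  size_t HW = (size_t)H * W;
  size_t NC = (size_t)N * Ctot;
  int at = 0;
  for (auto& t : ts) {
    size_t NCt = (size_t)N * t->C;
    for (size_t j = 0; j < HW; ++j)
      std::memcpy(y->v.data() + NC * j + (size_t)N * at,
                  t->v.data() + NCt * j, (size_t)N * t->C * sizeof(float));
    at += t->C;
  }
  return wrap_ft(y);
}

// channels [c0, c1] 1-based inclusive
// [[Rcpp::export(rng = false)]]
SEXP ft_slice_channels(SEXP xp, int c0, int c1) {
  FTP x(xp);
  int N = x->N, C = x->C, H = x->H, W = x->W;
  int Cs = c1 - c0 + 1;
  FT* y = new FT(N, Cs, H, W);
  size_t HW = (size_t)H * W;
  for (size_t j = 0; j < HW; ++j)
    std::memcpy(y->v.data() + (size_t)N * Cs * j,
                x->v.data() + (size_t)N * C * j + (size_t)N * (c0 - 1),
                (size_t)N * Cs * sizeof(float));
  return wrap_ft(y);
}

// [[Rcpp::export(rng = false)]]
SEXP ft_perm_channels(SEXP xp, IntegerVector perm) {
  FTP x(xp);
  int N = x->N, C = x->C, H = x->H, W = x->W;
  FT* y = new FT(N, C, H, W);
  size_t HW = (size_t)H * W;
  size_t NC = (size_t)N * C;
  for (size_t j = 0; j < HW; ++j)
    for (int c = 0; c < C; ++c)
      std::memcpy(y->v.data() + NC * j + (size_t)N * c,
                  x->v.data() + NC * j + (size_t)N * (perm[c] - 1),
                  N * sizeof(float));
  return wrap_ft(y);
}

// [[Rcpp::export(rng = false)]]
SEXP ft_upsample2_fw(SEXP xp) {
  FTP x(xp);
  int N = x->N, C = x->C, H = x->H, W = x->W;
  FT* y = new FT(N, C, 2 * H, 2 * W);
  size_t NC = (size_t)N * C;
  for (int w = 0; w < 2 * W; ++w)
    for (int h = 0; h < 2 * H; ++h)
      std::memcpy(y->v.data() + NC * (h + (size_t)2 * H * w),
                  x->v.data() + NC * (h / 2 + (size_t)H * (w / 2)),
                  NC * sizeof(float));
  return wrap_ft(y);
}

// [[Rcpp::export(rng = false)]]
SEXP ft_upsample2_bw(SEXP dyp) {
  FTP dy(dyp);
  int N = dy->N, C = dy->C, H2 = dy->H, W2 = dy->W;
  int H = H2 / 2, W = W2 / 2;
  FT* dx = new FT(N, C, H, W);
  size_t NC = (size_t)N * C;
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h) {
      const float* s = dy->v.data() + NC * (h + (size_t)H2 * w);
      float* d = dx->v.data() + NC * (h / 2 + (size_t)H * (w / 2));
      for (size_t i = 0; i < NC; ++i) d[i] += s[i];
    }
  return wrap_ft(dx);
}

// [[Rcpp::export(rng = false)]]
List ft_maxpool_fw(SEXP xp, int k) {
  FTP x(xp);
  int N = x->N, C = x->C, H = x->H, W = x->W;
  int pad = (k - 1) / 2;
  FT* y = new FT(N, C, H, W);
  XPtr<std::vector<int>> arg(new std::vector<int>(x->size()), true);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          float best = -INFINITY; size_t bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            int iw = w - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int ih = h - pad + kh;
              if (ih < 0 || ih >= H) continue;
              size_t xi = n + (size_t)N * (c + (size_t)C * (ih + (size_t)H * iw));
              if (x->v[xi] > best) { best = x->v[xi]; bi = xi; }
            }
          }
          size_t yi = n + (size_t)N * (c + (size_t)C * (h + (size_t)H * w));
          y->v[yi] = best;
          (*arg)[yi] = (int)bi;
        }
  return List::create(_["y"] = wrap_ft(y), _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
SEXP ft_maxpool_bw(SEXP dyp, SEXP argp) {
  FTP dy(dyp);
  XPtr<std::vector<int>> arg(argp);
  FT* dx = new FT(dy->N, dy->C, dy->H, dy->W);
  for (size_t i = 0; i < dy->size(); ++i) dx->v[(*arg)[i]] += dy->v[i];
  return wrap_ft(dx);
}

// per-(n,c) spatial mean -> N x C double matrix
// [[Rcpp::export(rng = false)]]
NumericMatrix ft_chan_mean(SEXP xp) {
  FTP x(xp);
  int N = x->N, C = x->C;
  size_t HW = (size_t)x->H * x->W;
  NumericMatrix m(N, C);
  size_t NC = (size_t)N * C;
  for (size_t j = 0; j < HW; ++j) {
    const float* p = x->v.data() + NC * j;
    for (size_t i = 0; i < NC; ++i) m[i] += p[i];
  }
  for (size_t i = 0; i < NC; ++i) m[i] /= HW;
  return m;
}

// per-(n,c) sum of a*b over spatial dims
// [[Rcpp::export(rng = false)]]
NumericMatrix ft_chan_dot(SEXP ap, SEXP bp) {
  FTP a(ap), b(bp);
  int N = a->N, C = a->C;
  size_t HW = (size_t)a->H * a->W;
  NumericMatrix m(N, C);
  size_t NC = (size_t)N * C;
  for (size_t j = 0; j < HW; ++j) {
    const float* p = a->v.data() + NC * j;
    const float* q = b->v.data() + NC * j;
    for (size_t i = 0; i < NC; ++i) m[i] += (double)p[i] * q[i];
  }
  return m;
}

// y = x * g[n,c] (+ addv[n,c] if given), g and addv are N x C
// [[Rcpp::export(rng = false)]]
SEXP ft_scale_channels(SEXP xp, NumericMatrix g, Nullable<NumericMatrix> addv) {
  FTP x(xp);
  int N = x->N, C = x->C;
  size_t HW = (size_t)x->H * x->W;
  size_t NC = (size_t)N * C;
  FT* y = new FT(N, C, x->H, x->W);
  std::vector<float> gf(NC), af(NC, 0.0f);
  for (size_t i = 0; i < NC; ++i) gf[i] = (float)g[i];
  bool hasAdd = addv.isNotNull();
  if (hasAdd) {
    NumericMatrix av(addv);
    for (size_t i = 0; i < NC; ++i) af[i] = (float)av[i];
  }
  for (size_t j = 0; j < HW; ++j) {
    const float* p = x->v.data() + NC * j;
    float* q = y->v.data() + NC * j;
    for (size_t i = 0; i < NC; ++i) q[i] = p[i] * gf[i] + af[i];
  }
  return wrap_ft(y);
}
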