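// Forward/backward kernels for the 3D convolutional encoder.
//
// Layer stack: four 3x3x3 stride-2 convolutions (pad 1), each followed by
// batch normalization and leaky ReLU, then two fully-connected layers
// (the first with batch norm + leaky ReLU, the second linear) producing the
// intermediary feature vector.  Convolutions are evaluated as im2col + GEMM.
// Activations and caches are single precision; parameters and gradients
// cross the R boundary as doubles.
//
// Memory layout: a batch of volumes arrives as an (S x B) double matrix,
// voxel index column-major (x fastest).  Internally layer activations are
// (C * S_l x B) with channel-fastest ordering, which aliases (C x S_l * B)
// for per-channel batch-norm statistics without copying.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct ConvGeom {
  int d1, d2, d3;     // input spatial dims
  int o1, o2, o3;     // output spatial dims
  int cin, cout;
  int S() const { return d1 * d2 * d3; }
  int P() const { return o1 * o2 * o3; }
  int pd1() const { return d1 + 2; }
  int pd2() const { return d2 + 2; }
  int pd3() const { return d3 + 2; }
  int Spad() const { return pd1() * pd2() * pd3(); }
};

inline int out_dim(int d) { return (d - 1) / 2 + 1; }

// zero-pad (cin x S x B, channel-fastest) -> (cin x Spad x B)
void pad_input(const fmat& x, fmat& xp, const ConvGeom& g) {
  xp.zeros();
  const int cin = g.cin, d1 = g.d1;
  for (arma::uword b = 0; b < x.n_cols; ++b) {
    const float* src = x.colptr(b);
    float* dst = xp.colptr(b);
    for (int z = 0; z < g.d3; ++z) {
      for (int y = 0; y < g.d2; ++y) {
        const int so = cin * (d1 * (y + g.d2 * z));
        const int dofs = cin * (1 + g.pd1() * ((y + 1) + g.pd2() * (z + 1)));
        std::memcpy(dst + dofs, src + so, sizeof(float) * cin * d1);
      }
    }
  }
}

// kernel-offset displacements in padded-flattened index units
inline void offset_deltas(const ConvGeom& g, int* delta) {
  int o = 0;
  for (int dz = 0; dz < 3; ++dz)
    for (int dy = 0; dy < 3; ++dy)
      for (int dx = 0; dx < 3; ++dx, ++o)
        delta[o] = dx + g.pd1() * (dy + g.pd2() * dz);
}

// im2col for 3x3x3 stride-2 kernels; col is (27*cin x P*B),
// row order: channel fastest within each of the 27 offsets.
void im2col(const fmat& xp, fmat& col, const ConvGeom& g) {
  const int cin = g.cin, P = g.P();
  const int pd1 = g.pd1(), pd2 = g.pd2();
  int delta[27];
  offset_deltas(g, delta);
  for (arma::uword b = 0; b < xp.n_cols; ++b) {
    const float* x = xp.colptr(b);
    float* cp = col.colptr((arma::uword)P * b);
    for (int oz = 0; oz < g.o3; ++oz)
      for (int oy = 0; oy < g.o2; ++oy) {
        const int rowbase = pd1 * (2 * oy + pd2 * 2 * oz);
        for (int ox = 0; ox < g.o1; ++ox, cp += 27 * cin) {
          const int base = 2 * ox + rowbase;
          if (cin == 1) {
            const float* xb = x + base;
            for (int o = 0; o < 27; ++o) cp[o] = xb[delta[o]];
          } else {
            for (int o = 0; o < 27; ++o) {
              const float* __restrict__ xs = x + (arma::uword)cin *
                                             (base + delta[o]);
              float* __restrict__ cd = cp + cin * o;
              for (int c = 0; c < cin; ++c) cd[c] = xs[c];
            }
          }
        }
      }
  }
}

// transpose of im2col: scatter-add col-gradients back onto the padded grid
void col2im(const fmat& dcol, fmat& dxp, const ConvGeom& g) {
  const int cin = g.cin, P = g.P();
  const int pd1 = g.pd1(), pd2 = g.pd2();
  int delta[27];
  offset_deltas(g, delta);
  dxp.zeros();
  for (arma::uword b = 0; b < dxp.n_cols; ++b) {
    float* x = dxp.colptr(b);
    const float* cp = dcol.colptr((arma::uword)P * b);
    for (int oz = 0; oz < g.o3; ++oz)
      for (int oy = 0; oy < g.o2; ++oy) {
        const int rowbase = pd1 * (2 * oy + pd2 * 2 * oz);
        for (int ox = 0; ox < g.o1; ++ox, cp += 27 * cin) {
          const int base = 2 * ox + rowbase;
          if (cin == 1) {
            float* xb = x + base;
            for (int o = 0; o < 27; ++o) xb[delta[o]] += cp[o];
          } else {
            for (int o = 0; o < 27; ++o) {
              float* __restrict__ xd = x + (arma::uword)cin *
                                       (base + delta[o]);
              const float* __restrict__ cs = cp + cin * o;
              for (int c = 0; c < cin; ++c) xd[c] += cs[c];
            }
          }
        }
      }
  }
}

void unpad(const fmat& dxp, fmat& dx, const ConvGeom& g) {
  const int cin = g.cin, d1 = g.d1;
  for (arma::uword b = 0; b < dx.n_cols; ++b) {
    const float* src = dxp.colptr(b);
    float* dst = dx.colptr(b);
    for (int z = 0; z < g.d3; ++z)
      for (int y = 0; y < g.d2; ++y) {
        const int dofs = cin * (d1 * (y + g.d2 * z));
        const int so = cin * (1 + g.pd1() * ((y + 1) + g.pd2() * (z + 1)));
        std::memcpy(dst + dofs, src + so, sizeof(float) * cin * d1);
      }
  }
}

// batch norm forward on z viewed as (C x M); writes xhat and a = lrelu(bn(z))
// in place of z when a == &z is allowed (we keep them separate for caching).
struct BNStats { fvec mean, invsd; };

BNStats bn_stats_train(const fmat& zview, int C, double eps) {
  const arma::uword M = zview.n_elem / C;
  fvec mu(C, arma::fill::zeros), ss(C, arma::fill::zeros);
  const float* z = zview.memptr();
  for (arma::uword j = 0; j < M; ++j) {
    const float* zc = z + (arma::uword)C * j;
    for (int c = 0; c < C; ++c) mu[c] += zc[c];
  }
  mu /= (double)M;
  for (arma::uword j = 0; j < M; ++j) {
    const float* zc = z + (arma::uword)C * j;
    for (int c = 0; c < C; ++c) {
      const float d = zc[c] - mu[c];
      ss[c] += d * d;
    }
  }
  BNStats st;
  st.mean = mu;
  st.invsd = 1.0f / arma::sqrt(ss / (float)M + (float)eps);
  return st;
}

void bn_lrelu_fwd(const fmat& z, fmat& xhat, fmat& a, int C,
                  const fvec& mean, const fvec& invsd,
                  const fvec& gamma, const fvec& beta, float slope) {
  const arma::uword M = z.n_elem / C;
  const float* zp = z.memptr();
  float* xh = xhat.memptr();
  float* ap = a.memptr();
  for (arma::uword j = 0; j < M; ++j) {
    const arma::uword off = (arma::uword)C * j;
    for (int c = 0; c < C; ++c) {
      const float h = (zp[off + c] - mean[c]) * invsd[c];
      xh[off + c] = h;
      const float y = gamma[c] * h + beta[c];
      ap[off + c] = y > 0.0f ? y : slope * y;
    }
  }
}

// train-statistics batch norm + lrelu applied in place (no caches kept)
void bn_lrelu_inplace(fmat& z, int C, const fvec& mean, const fvec& invsd,
                      const fvec& gamma, const fvec& beta, float slope) {
  const arma::uword M = z.n_elem / C;
  float* zp = z.memptr();
  for (arma::uword j = 0; j < M; ++j) {
    const arma::uword off = (arma::uword)C * j;
    for (int c = 0; c < C; ++c) {
      const float y = gamma[c] * (zp[off + c] - mean[c]) * invsd[c] + beta[c];
      zp[off + c] = y > 0.0f ? y : slope * y;
    }
  }
}

// backward through lrelu + batch norm; consumes dA (in `da`), writes dZ into
// `da` in place, accumulates dgamma/dbeta.
void bn_lrelu_bwd(fmat& da, const fmat& a, const fmat& xhat, int C,
                  const fvec& invsd, const fvec& gamma, float slope,
                  fvec& dgamma, fvec& dbeta) {
  const arma::uword M = da.n_elem / C;
  float* d = da.memptr();
  const float* ap = a.memptr();
  const float* xh = xhat.memptr();
  fvec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (arma::uword j = 0; j < M; ++j) {
    const arma::uword off = (arma::uword)C * j;
    for (int c = 0; c < C; ++c) {
      float dy = d[off + c] * (ap[off + c] > 0.0f ? 1.0f : slope);
      d[off + c] = dy;
      s1[c] += dy;
      s2[c] += dy * xh[off + c];
    }
  }
  dgamma = s2;
  dbeta = s1;
  const float invM = 1.0f / (float)M;
  for (arma::uword j = 0; j < M; ++j) {
    const arma::uword off = (arma::uword)C * j;
    for (int c = 0; c < C; ++c) {
      d[off + c] = gamma[c] * invsd[c] *
                   (d[off + c] - s1[c] * invM - xh[off + c] * s2[c] * invM);
    }
  }
}

void bn_eval_lrelu(fmat& z, int C, const fvec& rmean, const fvec& rvar,
                   const fvec& gamma, const fvec& beta, double eps,
                   float slope) {
  const arma::uword M = z.n_elem / C;
  fvec invsd = 1.0f / arma::sqrt(rvar + (float)eps);
  float* zp = z.memptr();
  for (arma::uword j = 0; j < M; ++j) {
    const arma::uword off = (arma::uword)C * j;
    for (int c = 0; c < C; ++c) {
      const float y = gamma[c] * (zp[off + c] - rmean[c]) * invsd[c] + beta[c];
      zp[off + c] = y > 0.0f ? y : slope * y;
    }
  }
}

struct EncCache {
  std::vector<ConvGeom> geom;
  std::vector<fmat> col;    // im2col buffers per conv layer
  std::vector<fmat> xhat;   // bn normalized activations per conv layer
  std::vector<fmat> act;    // post-lrelu activations per conv layer
  std::vector<fvec> invsd;
  std::vector<fmat> W;      // conv weights
  std::vector<fvec> gamma;
  fmat Wd1, Wd2;
  fmat xhat_d1, act_d1;
  fvec invsd_d1, gamma_d1;
  float slope;
  int B, feature_dim, flat_dim;
};

fmat as_f(const NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  const double* s = REAL(m);
  float* d = out.memptr();
  for (R_xlen_t i = 0; i < (R_xlen_t)m.nrow() * m.ncol(); ++i) d[i] = (float)s[i];
  return out;
}

fvec as_fv(const NumericVector& v) {
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

NumericMatrix to_d(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  double* d = REAL(out);
  const float* s = m.memptr();
  for (arma::uword i = 0; i < m.n_elem; ++i) d[i] = (double)s[i];
  return out;
}

NumericVector to_dv(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_enc_forward(NumericMatrix X, List params, IntegerVector input_shape,
                     IntegerVector channels, int feature_dim, bool train,
                     double momentum, double bn_eps, double slope,
                     bool want_cache) {
  const int B = X.ncol();
  const int n_conv = channels.size();
  List conv = params["conv"];
  List dense = params["dense"];

  std::unique_ptr<EncCache> cache(new EncCache());
  cache->slope = (float)slope;
  cache->B = B;
  cache->feature_dim = feature_dim;

  // layer geometries
  int d1 = input_shape[0], d2 = input_shape[1], d3 = input_shape[2];
  int cin = 1;
  for (int l = 0; l < n_conv; ++l) {
    ConvGeom g;
    g.d1 = d1; g.d2 = d2; g.d3 = d3;
    g.o1 = out_dim(d1); g.o2 = out_dim(d2); g.o3 = out_dim(d3);
    g.cin = cin; g.cout = channels[l];
    cache->geom.push_back(g);
    d1 = g.o1; d2 = g.o2; d3 = g.o3;
    cin = g.cout;
  }

  List run_mean(n_conv + 1), run_var(n_conv + 1);

  fmat A = as_f(X);  // (1*S x B)
  for (int l = 0; l < n_conv; ++l) {
    const ConvGeom& g = cache->geom[l];
    List lay = conv[l];
    fmat W = as_f(lay["W"]);
    fvec b = as_fv(lay["b"]);
    fvec gamma = as_fv(lay["gamma"]);
    fvec beta = as_fv(lay["beta"]);

    fmat xp(g.cin * g.Spad(), B);
    pad_input(A, xp, g);
    fmat col(27 * g.cin, (arma::uword)g.P() * B);
    im2col(xp, col, g);
    fmat Z = W * col;
    Z.each_col() += b;

    if (train) {
      BNStats st = bn_stats_train(Z, g.cout, bn_eps);
      fvec rm = as_fv(lay["run_mean"]), rv = as_fv(lay["run_var"]);
      fvec var = 1.0f / arma::square(st.invsd) - (float)bn_eps;
      rm = (float)momentum * rm + (1.0f - (float)momentum) * st.mean;
      rv = (float)momentum * rv + (1.0f - (float)momentum) * var;
      run_mean[l] = to_dv(rm);
      run_var[l] = to_dv(rv);
      if (want_cache) {
        fmat xh(Z.n_rows, Z.n_cols), Aout(Z.n_rows, Z.n_cols);
        bn_lrelu_fwd(Z, xh, Aout, g.cout, st.mean, st.invsd, gamma, beta,
                     (float)slope);
        cache->col.push_back(std::move(col));
        cache->xhat.push_back(std::move(xh));
        cache->act.push_back(Aout);
        cache->invsd.push_back(st.invsd);
        cache->W.push_back(std::move(W));
        cache->gamma.push_back(gamma);
        A = std::move(Aout);
      } else {
        bn_lrelu_inplace(Z, g.cout, st.mean, st.invsd, gamma, beta,
                         (float)slope);
        A = std::move(Z);
      }
    } else {
      bn_eval_lrelu(Z, g.cout, as_fv(lay["run_mean"]), as_fv(lay["run_var"]),
                    gamma, beta, bn_eps, (float)slope);
      A = std::move(Z);
    }
    // A is (cout x P*B) which aliases (cout*P x B) for the next layer
    A.reshape((arma::uword)g.cout * g.P(), B);
  }

  // dense head
  List d1l = dense[0], d2l = dense[1];
  fmat Wd1 = as_f(d1l["W"]);
  fvec bd1 = as_fv(d1l["b"]);
  fvec gammad1 = as_fv(d1l["gamma"]);
  fvec betad1 = as_fv(d1l["beta"]);
  cache->flat_dim = A.n_rows;
  fmat Z1 = Wd1 * A;
  Z1.each_col() += bd1;
  if (train) {
    BNStats st = bn_stats_train(Z1, feature_dim, bn_eps);
    fvec rm = as_fv(d1l["run_mean"]), rv = as_fv(d1l["run_var"]);
    fvec var = 1.0f / arma::square(st.invsd) - (float)bn_eps;
    rm = (float)momentum * rm + (1.0f - (float)momentum) * st.mean;
    rv = (float)momentum * rv + (1.0f - (float)momentum) * var;
    run_mean[n_conv] = to_dv(rm);
    run_var[n_conv] = to_dv(rv);
    if (want_cache) {
      fmat xh(Z1.n_rows, Z1.n_cols), A1(Z1.n_rows, Z1.n_cols);
      bn_lrelu_fwd(Z1, xh, A1, feature_dim, st.mean, st.invsd, gammad1,
                   betad1, (float)slope);
      // keep flattened conv output for the dense weight gradient
      cache->act.push_back(A);
      cache->xhat_d1 = std::move(xh);
      cache->act_d1 = A1;
      cache->invsd_d1 = st.invsd;
      cache->gamma_d1 = gammad1;
      cache->Wd1 = Wd1;
      A = std::move(A1);
    } else {
      bn_lrelu_inplace(Z1, feature_dim, st.mean, st.invsd, gammad1, betad1,
                       (float)slope);
      A = std::move(Z1);
    }
  } else {
    bn_eval_lrelu(Z1, feature_dim, as_fv(d1l["run_mean"]),
                  as_fv(d1l["run_var"]), gammad1, betad1, bn_eps,
                  (float)slope);
    A = std::move(Z1);
  }

  fmat Wd2 = as_f(d2l["W"]);
  fvec bd2 = as_fv(d2l["b"]);
  fmat F = Wd2 * A;
  F.each_col() += bd2;
  if (want_cache && train) cache->Wd2 = std::move(Wd2);

  List out = List::create(_["features"] = to_d(F),
                          _["run_mean"] = run_mean,
                          _["run_var"] = run_var);
  if (want_cache && train) {
    XPtr<EncCache> ptr(cache.release(), true);
    out["cache"] = ptr;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_enc_backward(SEXP cache_ptr, NumericMatrix dF) {
  XPtr<EncCache> cache(cache_ptr);
  const int n_conv = cache->geom.size();
  const float slope = cache->slope;

  fmat d = as_f(dF);  // (feature_dim x B)

  // dense layer 2 (linear)
  fmat d2_dW = d * cache->act_d1.t();
  fvec d2_db = arma::sum(d, 1);
  fmat dA1 = cache->Wd2.t() * d;

  // dense layer 1 (+ BN + lrelu)
  fvec d1_dgamma, d1_dbeta;
  bn_lrelu_bwd(dA1, cache->act_d1, cache->xhat_d1, cache->feature_dim,
               cache->invsd_d1, cache->gamma_d1, slope, d1_dgamma, d1_dbeta);
  const fmat& Aflat = cache->act[n_conv];  // flattened conv output
  fmat d1_dW = dA1 * Aflat.t();
  fvec d1_db = arma::sum(dA1, 1);
  fmat dA = cache->Wd1.t() * dA1;  // (flat_dim x B)

  List conv_dW(n_conv), conv_db(n_conv), conv_dgamma(n_conv),
      conv_dbeta(n_conv);
  for (int l = n_conv - 1; l >= 0; --l) {
    const ConvGeom& g = cache->geom[l];
    // view as (cout x P*B)
    dA.reshape(g.cout, (arma::uword)g.P() * cache->B);
    fvec dgamma, dbeta;
    bn_lrelu_bwd(dA, cache->act[l], cache->xhat[l], g.cout, cache->invsd[l],
                 cache->gamma[l], slope, dgamma, dbeta);
    conv_dgamma[l] = to_dv(dgamma);
    conv_dbeta[l] = to_dv(dbeta);
    conv_db[l] = to_dv(arma::sum(dA, 1));
    conv_dW[l] = to_d(dA * cache->col[l].t());
    if (l > 0) {
      fmat dcol = cache->W[l].t() * dA;
      fmat dxp(g.cin * g.Spad(), cache->B);
      col2im(dcol, dxp, g);
      fmat dx(g.cin * g.S(), cache->B);
      unpad(dxp, dx, g);
      dA = std::move(dx);
    }
  }

  return List::create(
      _["conv_dW"] = conv_dW, _["conv_db"] = conv_db,
      _["conv_dgamma"] = conv_dgamma, _["conv_dbeta"] = conv_dbeta,
      _["d1_dW"] = to_d(d1_dW), _["d1_db"] = to_dv(d1_db),
      _["d1_dgamma"] = to_dv(d1_dgamma), _["d1_dbeta"] = to_dv(d1_dbeta),
      _["d2_dW"] = to_d(d2_dW), _["d2_db"] = to_dv(d2_db));
}

// Training allocates and frees tens of megabytes of im2col/activation
// buffers per gradient step; with glibc defaults these round-trip through
// mmap/munmap and the page faults dominate the step time.  Raising the
// mmap/trim thresholds lets the allocator recycle the blocks.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// Free the (large) backward buffers of a forward cache as soon as the
// backward pass has consumed them, without waiting for R's garbage
// collector to run the external-pointer finalizer.
// [[Rcpp::export]]
void cpp_enc_cache_release(SEXP cache_ptr) {
  XPtr<EncCache> cache(cache_ptr);
  cache->col.clear();
  cache->xhat.clear();
  cache->act.clear();
  cache->invsd.clear();
  cache->W.clear();
  cache->gamma.clear();
  cache->xhat_d1.reset();
  cache->act_d1.reset();
  cache->Wd1.reset();
  cache->Wd2.reset();
}

// Separable Gaussian blur along each axis of a 3D volume (used by the
// phantom simulator for the age/smoothness confound).  Truncated at 3 sigma,
// kernel renormalized at the edges.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector shape,
                               double sigma) {
  const int d1 = shape[0], d2 = shape[1], d3 = shape[2];
  if (sigma <= 0) return clone(vol);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + r];
  }
  for (auto& v : k) v /= ks;

  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int strides[3] = {1, d1, d1 * d2};
  const int dims[3] = {d1, d2, d3};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = dims[ax], st = strides[ax];
    const int nline = d1 * d2 * d3 / n;
    for (int line = 0; line < nline; ++line) {
      // compute base offset of this line
      int idx = line, base = 0;
      for (int o = 0; o < 3; ++o) {
        if (o == ax) continue;
        const int dd = dims[o];
        base += (idx % dd) * strides[o];
        idx /= dd;
      }
      for (int i = 0; i < n; ++i) {
        double s = 0, wsum = 0;
        const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          const double w = k[j - i + r];
          s += w * a[base + j * st];
          wsum += w;
        }
        b[base + i * st] = s / wsum;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}
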