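// Compact CNN engine for scalogram classification.
//
// Architecture (per branch): two valid-mode 2D convolutions with 32 kernels
// each (kernel k x k, stride 1), ReLU, 2x2 average pooling (stride 2) and
// dropout after each pooling stage, a 256-unit ReLU dense layer with
// dropout, and a 2-unit softmax output. Convolutions are evaluated as
// im2col + GEMM so the heavy lifting runs on BLAS; internal arithmetic is
// single precision (the optimizer accumulates in double on the R side).
//
// Layout conventions: images are H x W column-major matrices; multi-channel
// activations are (n_pixels x n_channels) matrices whose columns are
// channel images (pixel index p = h + H * w); conv weights are
// (k*k*C_in) x C_out with row index r = ki + k*kj + k*k*c.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int H1, W1, Hp1, Wp1, H2, W2, Hp2, Wp2, flat;
};

Dims layer_dims(int H, int W, int k) {
  Dims d;
  d.H1 = H - k + 1; d.W1 = W - k + 1;
  d.Hp1 = d.H1 / 2; d.Wp1 = d.W1 / 2;
  d.H2 = d.Hp1 - k + 1; d.W2 = d.Wp1 - k + 1;
  d.Hp2 = d.H2 / 2; d.Wp2 = d.W2 / 2;
  d.flat = d.Hp2 * d.Wp2 * 32;
  return d;
}

// X: (H x W x C) fcube; cols: (H2*W2) x (k*k*C), preallocated.
void im2col(const fcube& X, int k, int H2, int W2, fmat& cols) {
  for (uword c = 0; c < X.n_slices; ++c) {
    const fmat& S = X.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        float* dst = cols.colptr(r);
        for (int w2 = 0; w2 < W2; ++w2)
          std::memcpy(dst + (size_t)H2 * w2, S.colptr(w2 + kj) + ki,
                      sizeof(float) * H2);
      }
    }
  }
}

// Scatter-add transpose of im2col: dcols (H2*W2 x k*k*C) -> dX (H x W x C).
void col2im(const fmat& dcols, int k, int H2, int W2, fcube& dX) {
  dX.zeros();
  for (uword c = 0; c < dX.n_slices; ++c) {
    fmat& S = dX.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        const float* src = dcols.colptr(r);
        for (int w2 = 0; w2 < W2; ++w2) {
          float* dst = S.colptr(w2 + kj) + ki;
          const float* s = src + (size_t)H2 * w2;
          for (int h2 = 0; h2 < H2; ++h2) dst[h2] += s[h2];
        }
      }
    }
  }
}

// A: (Hin*Win x C) channel-column activations -> P: (Hp*Wp x C), 2x2 mean.
void avgpool(const fmat& A, int Hin, int Hp, int Wp, fmat& P) {
  for (uword c = 0; c < A.n_cols; ++c) {
    const float* a = A.colptr(c);
    float* p = P.colptr(c);
    for (int wp = 0; wp < Wp; ++wp) {
      const float* c0 = a + (size_t)Hin * (2 * wp);
      const float* c1 = a + (size_t)Hin * (2 * wp + 1);
      float* pc = p + (size_t)Hp * wp;
      for (int hp = 0; hp < Hp; ++hp)
        pc[hp] = 0.25f * (c0[2 * hp] + c0[2 * hp + 1] +
                          c1[2 * hp] + c1[2 * hp + 1]);
    }
  }
}

void avgpool_back(const fmat& dP, int Hin, int Hp, int Wp, fmat& dA) {
  dA.zeros();
  for (uword c = 0; c < dA.n_cols; ++c) {
    const float* dp = dP.colptr(c);
    float* da = dA.colptr(c);
    for (int wp = 0; wp < Wp; ++wp) {
      float* c0 = da + (size_t)Hin * (2 * wp);
      float* c1 = da + (size_t)Hin * (2 * wp + 1);
      const float* pc = dp + (size_t)Hp * wp;
      for (int hp = 0; hp < Hp; ++hp) {
        const float g = 0.25f * pc[hp];
        c0[2 * hp] += g; c0[2 * hp + 1] += g;
        c1[2 * hp] += g; c1[2 * hp + 1] += g;
      }
    }
  }
}

inline void relu_(fmat& A) {
  float* a = A.memptr();
  for (uword i = 0; i < A.n_elem; ++i)
    if (a[i] < 0) a[i] = 0;
}

// Zero dg where the forward activation was clipped (a == 0 after ReLU).
inline void relu_mask_(fmat& dg, const fmat& a) {
  float* d = dg.memptr();
  const float* p = a.memptr();
  for (uword i = 0; i < dg.n_elem; ++i)
    if (p[i] <= 0) d[i] = 0;
}

void dropout_mask(fmat& M, double rate, std::mt19937& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const float inv_keep = (float)(1.0 / (1.0 - rate));
  float* m = M.memptr();
  for (uword i = 0; i < M.n_elem; ++i)
    m[i] = (U(rng) < 1.0 - rate) ? inv_keep : 0.0f;
}

fmat as_f(const Rcpp::List& params, const char* name) {
  return conv_to<fmat>::from(Rcpp::as<mat>(params[name]));
}
fvec as_fv(const Rcpp::List& params, const char* name) {
  return conv_to<fvec>::from(Rcpp::as<vec>(params[name]));
}

} // namespace

// Forward pass without dropout (inference). Returns B x 2 softmax matrix.
// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const Rcpp::List& params, const arma::cube& Xin,
                          int k) {
  const fmat W1 = as_f(params, "W1"); const fvec b1 = as_fv(params, "b1");
  const fmat W2 = as_f(params, "W2"); const fvec b2 = as_fv(params, "b2");
  const fmat Wd = as_f(params, "Wd"); const fvec bd = as_fv(params, "bd");
  const fmat Wo = as_f(params, "Wo"); const fvec bo = as_fv(params, "bo");
  const fcube X = conv_to<fcube>::from(Xin);
  const int H = X.n_rows, W = X.n_cols, B = X.n_slices;
  Dims d = layer_dims(H, W, k);
  const int np1 = d.H1 * d.W1, np2 = d.H2 * d.W2;

  fmat cols1(np1, k * k), A1(np1, 32), P1(d.Hp1 * d.Wp1, 32);
  fmat cols2(np2, k * k * 32), A2(np2, 32), P2(d.Hp2 * d.Wp2, 32);
  mat probs(B, 2);

  for (int b = 0; b < B; ++b) {
    fcube x1(const_cast<float*>(X.slice(b).memptr()), H, W, 1, false);
    im2col(x1, k, d.H1, d.W1, cols1);
    A1 = cols1 * W1;
    A1.each_row() += b1.t();
    relu_(A1);
    avgpool(A1, d.H1, d.Hp1, d.Wp1, P1);
    fcube p1c(P1.memptr(), d.Hp1, d.Wp1, 32, false);
    im2col(p1c, k, d.H2, d.W2, cols2);
    A2 = cols2 * W2;
    A2.each_row() += b2.t();
    relu_(A2);
    avgpool(A2, d.H2, d.Hp2, d.Wp2, P2);
    fvec flat(P2.memptr(), P2.n_elem, false);
    fvec h = Wd.t() * flat + bd;
    relu_(reinterpret_cast<fmat&>(h));
    fvec o = Wo * h + bo;
    double e0 = std::exp((double)o[0] - (double)o.max());
    double e1 = std::exp((double)o[1] - (double)o.max());
    probs(b, 0) = e0 / (e0 + e1);
    probs(b, 1) = e1 / (e0 + e1);
  }
  return probs;
}

// One mini-batch forward+backward. Returns mean gradients, mean loss,
// accuracy, and the softmax outputs. y holds class indices (0 = other,
// 1 = arrhythmia).
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(const Rcpp::List& params, const arma::cube& Xin,
                        const arma::ivec& y, int k, double dropout,
                        int rng_seed) {
  const fmat W1 = as_f(params, "W1"); const fvec b1 = as_fv(params, "b1");
  const fmat W2 = as_f(params, "W2"); const fvec b2 = as_fv(params, "b2");
  const fmat Wd = as_f(params, "Wd"); const fvec bd = as_fv(params, "bd");
  const fmat Wo = as_f(params, "Wo"); const fvec bo = as_fv(params, "bo");
  const fcube X = conv_to<fcube>::from(Xin);
  const int H = X.n_rows, W = X.n_cols, B = X.n_slices;
  Dims d = layer_dims(H, W, k);
  const int np1 = d.H1 * d.W1, np2 = d.H2 * d.W2;
  const int npp1 = d.Hp1 * d.Wp1, npp2 = d.Hp2 * d.Wp2;
  const int nh = bd.n_elem;

  std::mt19937 rng(rng_seed);

  fmat gW1(size(W1), fill::zeros), gW2(size(W2), fill::zeros);
  fvec gb1(32, fill::zeros), gb2(32, fill::zeros);
  // dense-layer gradients are assembled batch-wise below
  fmat Flat(d.flat, B), Dh(nh, B), Hact(nh, B), dOut(2, B);

  fmat cols1(np1, k * k), A1(np1, 32), P1(npp1, 32), D1(npp1, 32);
  fmat cols2(np2, k * k * 32), A2(np2, 32), P2(npp2, 32), D2(npp2, 32);
  fmat dA1(np1, 32), dA2(np2, 32), dP1(npp1, 32), dP2(npp2, 32);
  fmat dcols2(np2, k * k * 32);
  fcube dP1cube(d.Hp1, d.Wp1, 32);
  fmat Dhmask(nh, B);
  mat probs(B, 2);
  double loss = 0.0;
  int n_correct = 0;
  const bool use_drop = dropout > 0;

  // masks for the dense stage are drawn per image in stream order together
  // with the conv-stage masks, so one seed fixes the whole batch
  for (int b = 0; b < B; ++b) {
    // forward
    fcube x1(const_cast<float*>(X.slice(b).memptr()), H, W, 1, false);
    im2col(x1, k, d.H1, d.W1, cols1);
    A1 = cols1 * W1;
    A1.each_row() += b1.t();
    relu_(A1);
    avgpool(A1, d.H1, d.Hp1, d.Wp1, P1);
    if (use_drop) { dropout_mask(D1, dropout, rng); P1 %= D1; }
    fcube p1c(P1.memptr(), d.Hp1, d.Wp1, 32, false);
    im2col(p1c, k, d.H2, d.W2, cols2);
    A2 = cols2 * W2;
    A2.each_row() += b2.t();
    relu_(A2);
    avgpool(A2, d.H2, d.Hp2, d.Wp2, P2);
    if (use_drop) { dropout_mask(D2, dropout, rng); P2 %= D2; }
    fvec flat(P2.memptr(), P2.n_elem, false);
    Flat.col(b) = flat;
    fvec hpre = Wd.t() * flat + bd;
    fvec h = hpre;
    relu_(reinterpret_cast<fmat&>(h));
    if (use_drop) {
      fmat mcol(Dhmask.colptr(b), nh, 1, false);
      dropout_mask(mcol, dropout, rng);
      h %= Dhmask.col(b);
    }
    Hact.col(b) = h;
    fvec o = Wo * h + bo;
    double e0 = std::exp((double)o[0] - (double)o.max());
    double e1 = std::exp((double)o[1] - (double)o.max());
    const double p0 = e0 / (e0 + e1), p1v = e1 / (e0 + e1);
    probs(b, 0) = p0; probs(b, 1) = p1v;
    const int yb = y[b];
    loss += -std::log(std::max(yb == 1 ? p1v : p0, 1e-12));
    if ((p1v > p0 ? 1 : 0) == yb) ++n_correct;

    // backward: output and dense layers (per-image pieces stored, heavy
    // GEMMs deferred to batch level)
    dOut(0, b) = (float)(p0 - (yb == 0 ? 1.0 : 0.0));
    dOut(1, b) = (float)(p1v - (yb == 1 ? 1.0 : 0.0));
    fvec dh = Wo.t() * fvec(dOut.colptr(b), 2);
    if (use_drop) dh %= Dhmask.col(b);
    relu_mask_(reinterpret_cast<fmat&>(dh), reinterpret_cast<fmat&>(hpre));
    Dh.col(b) = dh;

    // backward: conv stack
    fvec dflat = Wd * dh;
    std::memcpy(dP2.memptr(), dflat.memptr(), sizeof(float) * dflat.n_elem);
    if (use_drop) dP2 %= D2;
    avgpool_back(dP2, d.H2, d.Hp2, d.Wp2, dA2);
    relu_mask_(dA2, A2);
    gW2 += cols2.t() * dA2;
    gb2 += sum(dA2, 0).t();
    dcols2 = dA2 * W2.t();
    col2im(dcols2, k, d.H2, d.W2, dP1cube);
    fmat dP1m(dP1cube.memptr(), npp1, 32, false);
    if (use_drop) dP1m %= D1;
    avgpool_back(dP1m, d.H1, d.Hp1, d.Wp1, dA1);
    relu_mask_(dA1, A1);
    gW1 += cols1.t() * dA1;
    gb1 += sum(dA1, 0).t();
  }

  const float s = 1.0f / B;
  fmat gWd = Flat * Dh.t() * s;
  fvec gbd = sum(Dh, 1) * s;
  fmat gWo = dOut * Hact.t() * s;
  fvec gbo = sum(dOut, 1) * s;

  return Rcpp::List::create(
    Rcpp::Named("gW1") = conv_to<mat>::from(gW1 * s),
    Rcpp::Named("gb1") = conv_to<vec>::from(gb1 * s),
    Rcpp::Named("gW2") = conv_to<mat>::from(gW2 * s),
    Rcpp::Named("gb2") = conv_to<vec>::from(gb2 * s),
    Rcpp::Named("gWd") = conv_to<mat>::from(gWd),
    Rcpp::Named("gbd") = conv_to<vec>::from(gbd),
    Rcpp::Named("gWo") = conv_to<mat>::from(gWo),
    Rcpp::Named("gbo") = conv_to<vec>::from(gbo),
    Rcpp::Named("loss") = loss / B,
    Rcpp::Named("accuracy") = (double)n_correct / B,
    Rcpp::Named("probs") = probs);
}

// In-place Adam step on a parameter vector/matrix and its moment buffers.
// All three R objects are modified directly (they are owned by the caller's
// optimizer state and never aliased).
// [[Rcpp::export]]
void adam_step_cpp(Rcpp::NumericVector w, Rcpp::NumericVector g,
                   Rcpp::NumericVector m, Rcpp::NumericVector v,
                   double lr, double beta1, double beta2, double eps,
                   double c1, double c2) {
  const R_xlen_t n = w.size();
  double* pw = REAL(w); const double* pg = REAL(g);
  double* pm = REAL(m); double* pv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pw[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}
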