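// Compact convolutional patch encoder and the fused attention-MIL
// training step.
//
// The encoder maps a d x d x 3 patch to an M-dimensional feature vector
// through four blocks of [3x3 stride-2 convolution -> per-instance
// (instance) normalisation with learned scale/shift -> ReLU], followed by
// global average pooling and a final linear layer. Instance normalisation
// (statistics over the spatial positions of each patch's channel map)
// keeps every feature row a function of its own patch only — the
// per-instance contract of the encoder — while giving the
// well-conditioned activations a from-scratch network needs at batch
// size one. Inputs are centred to [-1, 1] on entry. A whole bag of K
// patches is processed as one batch so each convolution is a single
// im2col GEMM.
//
// mil_step_cpp() runs the full forward pass (encoder, additive attention
// pooling, linear classifier, binary cross-entropy) and the full backward
// pass in one call, keeping all activation caches in C++ memory; this is
// the training hot path.
//
// Layout conventions (all column-major, matching R arrays):
//   * a bag arrives as an R array [d, d, 3, K];
//   * internally every activation is a "block matrix": one column per
//     channel, rows indexed k*(h*h) + j*h + i for sample k and spatial
//     position (i, j) — so layer outputs feed the next layer's im2col
//     with no intermediate reshaping;
//   * im2col matrices have one row per (sample, output position) with row
//     index k*(oh*ow) + oj*oh + oi, and one column per (channel, kernel
//     offset) with column index c*kh*kw + kj*kh + ki;
//   * convolution weights are (Cin*kh*kw) x Cout matrices in the same
//     column order; per-channel norm scales g and shifts b are 1 x Cout.

#define ARMA_NO_DEBUG  // hot path: element accessors without bounds checks
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int KH = 3, KW = 3, STRIDE = 2, PAD = 1;
static const int N_CONV = 4;
static const double IN_EPS = 1e-5;

static inline int out_dim(int n) { return (n + 2 * PAD - KH) / STRIDE + 1; }

// im2col on a block matrix A (rows k*h*h + j*h + i, one column per
// channel).
static mat im2col(const mat& A, int K, int h, int C) {
  const int oh = out_dim(h);
  mat M(static_cast<uword>(K) * oh * oh, static_cast<uword>(C) * KH * KW,
        fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* ac = A.colptr(c);
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        double* mc = M.colptr(c * KH * KW + kj * KH + ki);
        for (int k = 0; k < K; ++k) {
          const double* blk = ac + static_cast<size_t>(k) * h * h;
          for (int oj = 0; oj < oh; ++oj) {
            const int j = oj * STRIDE - PAD + kj;
            if (j < 0 || j >= h) continue;
            double* dst = mc + static_cast<size_t>(k) * oh * oh + oj * oh;
            const double* src = blk + static_cast<size_t>(j) * h;
            for (int oi = 0; oi < oh; ++oi) {
              const int i = oi * STRIDE - PAD + ki;
              if (i < 0 || i >= h) continue;
              dst[oi] = src[i];
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add transpose of im2col back onto a block matrix of spatial
// size h with C channels.
static mat col2im(const mat& dM, int h, int K, int C) {
  const int oh = out_dim(h);
  mat dA(static_cast<uword>(K) * h * h, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* ac = dA.colptr(c);
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const double* mc = dM.colptr(c * KH * KW + kj * KH + ki);
        for (int k = 0; k < K; ++k) {
          double* blk = ac + static_cast<size_t>(k) * h * h;
          for (int oj = 0; oj < oh; ++oj) {
            const int j = oj * STRIDE - PAD + kj;
            if (j < 0 || j >= h) continue;
            const double* src = mc + static_cast<size_t>(k) * oh * oh +
                                oj * oh;
            double* dst = blk + static_cast<size_t>(j) * h;
            for (int oi = 0; oi < oh; ++oi) {
              const int i = oi * STRIDE - PAD + ki;
              if (i < 0 || i >= h) continue;
              dst[i] += src[oi];
            }
          }
        }
      }
    }
  }
  return dA;
}

// Instance-normalise each (sample, channel) block of Z in place; returns
// the per-block inverse standard deviations (K x C). Z has K*n rows.
static mat instnorm(mat& Z, int K, int n) {
  const int C = Z.n_cols;
  mat inv_sd(K, C);
  for (int c = 0; c < C; ++c) {
    double* z = Z.colptr(c);
    for (int k = 0; k < K; ++k) {
      double* x = z + static_cast<size_t>(k) * n;
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        s1 += x[i];
        s2 += x[i] * x[i];
      }
      const double mu = s1 / n;
      const double v = s2 / n - mu * mu;
      const double is = 1.0 / std::sqrt((v > 0 ? v : 0) + IN_EPS);
      for (int i = 0; i < n; ++i) x[i] = (x[i] - mu) * is;
      inv_sd(k, c) = is;
    }
  }
  return inv_sd;
}

struct LayerCache {
  mat cols;   // im2col input
  mat yhat;   // normalised pre-affine activations
  mat isd;    // K x Cout inverse sds
  mat out;    // post-ReLU output (block matrix)
};

struct EncoderOut {
  mat H;  // K x M features
  mat P;  // K x C_last pooled activations
};

// Convert the R bag array [d, d, C0, K] (slice order c within k) to the
// internal block-matrix layout, centring intensities to [-1, 1].
static mat input_blocks(const double* x, int d, int C0, int K) {
  mat A(static_cast<uword>(K) * d * d, C0);
  const size_t plane = static_cast<size_t>(d) * d;
  for (int c = 0; c < C0; ++c) {
    double* ac = A.colptr(c);
    for (int k = 0; k < K; ++k) {
      const double* src = x + plane * (c + static_cast<size_t>(C0) * k);
      double* dst = ac + plane * k;
      for (size_t p = 0; p < plane; ++p) dst[p] = 2.0 * (src[p] - 0.5);
    }
  }
  return A;
}

// Shared encoder forward; fills caches when requested.
static EncoderOut encoder_forward(const double* x, int d, int C0, int K,
                                  const Rcpp::List& params,
                                  std::vector<LayerCache>* caches) {
  mat cur = input_blocks(x, d, C0, K);
  int h = d;
  int C = C0;
  for (int l = 0; l < N_CONV; ++l) {
    const mat W = Rcpp::as<mat>(params[std::string("W") + char('1' + l)]);
    const rowvec g =
        Rcpp::as<rowvec>(params[std::string("g") + char('1' + l)]);
    const rowvec b =
        Rcpp::as<rowvec>(params[std::string("b") + char('1' + l)]);
    const int Cout = W.n_cols;
    const int oh = out_dim(h);
    mat Mc = im2col(cur, K, h, C);
    mat Z = Mc * W;
    mat isd = instnorm(Z, K, oh * oh);  // Z becomes Yhat
    mat O = Z;
    O.each_row() %= g;
    O.each_row() += b;
    O.clamp(0.0, datum::inf);  // ReLU
    if (caches) {
      (*caches)[l].cols = std::move(Mc);
      (*caches)[l].yhat = std::move(Z);
      (*caches)[l].isd = std::move(isd);
      (*caches)[l].out = O;
    }
    cur = std::move(O);
    h = oh;
    C = Cout;
  }

  // global average pooling over the final h x h grid
  EncoderOut eo;
  eo.P.set_size(K, C);
  const int n = h * h;
  for (int c = 0; c < C; ++c) {
    const double* oc = cur.colptr(c);
    for (int k = 0; k < K; ++k) {
      const vec blk(const_cast<double*>(oc + static_cast<size_t>(k) * n),
                    n, false, true);
      eo.P(k, c) = accu(blk) / n;
    }
  }

  const mat Wf = Rcpp::as<mat>(params["Wf"]);
  const rowvec bf = Rcpp::as<rowvec>(params["bf"]);
  eo.H = eo.P * Wf;
  eo.H.each_row() += bf;
  return eo;
}

// Forward pass over a bag: x is an R array [d, d, C0, K]; returns the
// K x M feature matrix H.
// [[Rcpp::export]]
Rcpp::List cnn_forward_cpp(Rcpp::NumericVector x, Rcpp::List params) {
  Rcpp::IntegerVector dims = x.attr("dim");
  const int d = dims[0], C0 = dims[2], K = dims[3];
  if (dims[1] != d) Rcpp::stop("patches must be square");
  EncoderOut eo = encoder_forward(x.begin(), d, C0, K, params, nullptr);
  return Rcpp::List::create(Rcpp::Named("H") = eo.H);
}

// Fused training step: forward (encoder + attention + classifier + BCE)
// and backward for one (bag, label) pair. Returns the loss, the bag
// probability, the attention weights and the gradient of every parameter.
// [[Rcpp::export]]
Rcpp::List mil_step_cpp(Rcpp::NumericVector x, double y, Rcpp::List params,
                        double eps) {
  Rcpp::IntegerVector dims = x.attr("dim");
  const int d = dims[0], C0 = dims[2], K = dims[3];
  if (dims[1] != d) Rcpp::stop("patches must be square");

  std::vector<LayerCache> caches(N_CONV);
  EncoderOut eo = encoder_forward(x.begin(), d, C0, K, params, &caches);

  // attention + classifier head
  const mat V = Rcpp::as<mat>(params["V"]);
  const vec w = Rcpp::as<vec>(params["w"]);
  const vec u = Rcpp::as<vec>(params["u"]);
  const double b0 = Rcpp::as<mat>(params["b0"])(0, 0);

  mat e = tanh(eo.H * V.t());           // K x L
  vec logits = e * w;
  vec a = exp(logits - logits.max());
  a /= accu(a);
  vec z = eo.H.t() * a;                 // M
  const double score = dot(z, u) + b0;
  const double p = 1.0 / (1.0 + std::exp(-score));
  const double pc = std::min(std::max(p, eps), 1.0 - eps);
  const double loss = -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));

  // head backward
  const double dscore = p - y;
  vec du = dscore * z;
  vec dz = dscore * u;
  vec dalpha = eo.H * dz;
  mat dH = a * dz.t();                  // K x M
  vec dlogits = a % (dalpha - dot(a, dalpha));
  vec dw = e.t() * dlogits;
  mat dE = (dlogits * w.t()) % (1.0 - square(e));
  mat dV = dE.t() * eo.H;
  dH += dE * V;

  Rcpp::List grads;
  grads["V"] = dV;
  grads["w"] = mat(dw);
  grads["u"] = mat(du);
  grads["b0"] = mat(1, 1, fill::value(dscore));

  // encoder backward
  const mat Wf = Rcpp::as<mat>(params["Wf"]);
  grads["Wf"] = eo.P.t() * dH;
  grads["bf"] = sum(dH, 0);
  mat dP = dH * Wf.t();

  int hs[N_CONV + 1];
  hs[0] = d;
  for (int l = 0; l < N_CONV; ++l) hs[l + 1] = out_dim(hs[l]);
  int cs[N_CONV + 1];
  cs[0] = C0;
  for (int l = 0; l < N_CONV; ++l)
    cs[l + 1] = Rcpp::as<mat>(params[std::string("W") + char('1' + l)]).n_cols;

  // un-pool: every spatial cell of the last activation shares dP / (h*h)
  const int hl = hs[N_CONV], Cl = cs[N_CONV];
  const int nl = hl * hl;
  mat dO(static_cast<uword>(K) * nl, Cl);
  for (int c = 0; c < Cl; ++c) {
    double* oc = dO.colptr(c);
    for (int k = 0; k < K; ++k) {
      const double v = dP(k, c) / nl;
      double* blk = oc + static_cast<size_t>(k) * nl;
      for (int p2 = 0; p2 < nl; ++p2) blk[p2] = v;
    }
  }

  for (int l = N_CONV - 1; l >= 0; --l) {
    const mat W = Rcpp::as<mat>(params[std::string("W") + char('1' + l)]);
    const rowvec g =
        Rcpp::as<rowvec>(params[std::string("g") + char('1' + l)]);
    const LayerCache& lc = caches[l];
    const int n = hs[l + 1] * hs[l + 1];
    const int Cout = cs[l + 1];

    // ReLU gate
    {
      const double* op = lc.out.memptr();
      double* dp = dO.memptr();
      const size_t nn = dO.n_elem;
      for (size_t q = 0; q < nn; ++q) {
        if (op[q] <= 0) dp[q] = 0.0;
      }
    }
    grads[std::string("g") + char('1' + l)] = sum(dO % lc.yhat, 0);
    grads[std::string("b") + char('1' + l)] = sum(dO, 0);

    // through the affine and the per-block normalisation
    mat dZ(dO.n_rows, Cout);
    for (int c = 0; c < Cout; ++c) {
      const double gc = g[c];
      const double* dyc = dO.colptr(c);
      const double* yhc = lc.yhat.colptr(c);
      double* dzc = dZ.colptr(c);
      for (int k = 0; k < K; ++k) {
        const size_t off = static_cast<size_t>(k) * n;
        double s1 = 0.0, s2 = 0.0;
        for (int i = 0; i < n; ++i) {
          const double dy = dyc[off + i] * gc;
          s1 += dy;
          s2 += dy * yhc[off + i];
        }
        const double m1 = s1 / n, m2 = s2 / n;
        const double is = lc.isd(k, c);
        for (int i = 0; i < n; ++i) {
          dzc[off + i] =
              (dyc[off + i] * gc - m1 - yhc[off + i] * m2) * is;
        }
      }
    }

    grads[std::string("W") + char('1' + l)] = lc.cols.t() * dZ;
    if (l > 0) {
      mat dM = dZ * W.t();
      dO = col2im(dM, hs[l], K, cs[l]);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("p") = p,
      Rcpp::Named("alpha") = Rcpp::NumericVector(a.begin(), a.end()),
      Rcpp::Named("grads") = grads);
}
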