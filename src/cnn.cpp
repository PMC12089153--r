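// Eight-block 1-D convolutional classifier: forward pass and analytic
// gradients. Layout: activations are (channels x time*batch) matrices,
// sample b occupying the contiguous column block [b*L, (b+1)*L).
// Convolutions are im2col + GEMM per sample; batch normalization is
// per-channel over all time points and samples of the minibatch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const float BN_EPS = 1e-5f;

static int conv_out_len(int L, int K, int stride, int pad) {
  return (L + 2 * pad - K) / stride + 1;
}

// fill col (C*K x L_out) from one sample's activation block (C x L)
static void im2col(const arma::fmat& A, int b, int L, int K, int stride,
                   int pad, arma::fmat& col) {
  const int C = A.n_rows;
  const int L_out = col.n_cols;
  for (int j = 0; j < L_out; ++j) {
    const int t0 = j * stride - pad;
    for (int k = 0; k < K; ++k) {
      const int t = t0 + k;
      if (t < 0 || t >= L) {
        for (int c = 0; c < C; ++c) col(c * K + k, j) = 0.0f;
      } else {
        for (int c = 0; c < C; ++c) col(c * K + k, j) = A(c, b * L + t);
      }
    }
  }
}

// scatter dcol (C*K x L_out) back into sample b of dA (C x L*B)
static void col2im(const arma::fmat& dcol, int b, int L, int K, int stride,
                   int pad, arma::fmat& dA) {
  const int C = dA.n_rows;
  const int L_out = dcol.n_cols;
  for (int j = 0; j < L_out; ++j) {
    const int t0 = j * stride - pad;
    for (int k = 0; k < K; ++k) {
      const int t = t0 + k;
      if (t < 0 || t >= L) continue;
      for (int c = 0; c < C; ++c) dA(c, b * L + t) += dcol(c * K + k, j);
    }
  }
}

struct BlockParams {
  arma::fmat W;          // C_out x C_in*K
  arma::fvec b, gamma, beta, rmean, rvar;
  int stride, K;
};

// manual double->float copy: Rcpp's generic converter is much slower for
// large arrays with element-type conversion
static arma::fcube cube_from_r(const NumericVector& X) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 3) stop("input batch must be a 3-d array");
  arma::fcube out(d[0], d[1], d[2]);
  const double* src = X.begin();
  float* dst = out.memptr();
  const size_t n = (size_t)d[0] * d[1] * d[2];
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static arma::fvec fvec_from_r(const NumericVector& v) {
  arma::fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static std::vector<BlockParams> unpack_blocks(const List& blocks) {
  std::vector<BlockParams> out;
  for (int i = 0; i < blocks.size(); ++i) {
    List bl = blocks[i];
    BlockParams p;
    p.W = as<arma::fmat>(bl["W"]);
    p.b = as<arma::fvec>(bl["b"]);
    p.gamma = as<arma::fvec>(bl["gamma"]);
    p.beta = as<arma::fvec>(bl["beta"]);
    p.rmean = as<arma::fvec>(bl["running_mean"]);
    p.rvar = as<arma::fvec>(bl["running_var"]);
    p.stride = as<int>(bl["stride"]);
    p.K = as<int>(bl["kernel"]);
    out.push_back(p);
  }
  return out;
}

struct ForwardCache {
  std::vector<arma::fmat> A;       // activations, A[0] = input
  std::vector<arma::fmat> xhat;    // BN-normalized pre-activations
  std::vector<arma::fvec> invstd, bmean, bvar;
  std::vector<int> Ls;            // temporal lengths per level
  arma::fmat feat;                 // pooled features C8 x B
  arma::umat argmax;              // for adaptive max pooling
  arma::fvec logits;
};

// use_batch[l]: BN uses minibatch statistics at block l (training mode);
// otherwise the stored running statistics are used (evaluation mode).
static ForwardCache forward_pass(const std::vector<BlockParams>& bp,
                                 const arma::fvec& head_w, double head_b,
                                 const arma::fcube& X,
                                 const std::vector<bool>& use_batch,
                                 int pooling, bool keep_cache) {
  const int B = X.n_slices, C0 = X.n_rows, L0 = X.n_cols;
  const int n_blocks = bp.size();
  ForwardCache fc;
  fc.Ls.resize(n_blocks + 1);
  fc.A.resize(n_blocks + 1);
  fc.xhat.resize(n_blocks + 1);
  fc.invstd.resize(n_blocks + 1);
  fc.bmean.resize(n_blocks + 1);
  fc.bvar.resize(n_blocks + 1);
  fc.Ls[0] = L0;
  arma::fmat A0(C0, (size_t)L0 * B);
  for (int b = 0; b < B; ++b) A0.cols((size_t)b * L0, (size_t)(b + 1) * L0 - 1) = X.slice(b);
  fc.A[0] = std::move(A0);

  for (int l = 0; l < n_blocks; ++l) {
    const BlockParams& p = bp[l];
    const int C_in = fc.A[l].n_rows;
    const int L_in = fc.Ls[l];
    const int L_out = conv_out_len(L_in, p.K, p.stride, p.K / 2);
    const int C_out = p.W.n_rows;
    if (L_out < 1) stop("temporal length collapsed below 1 at block %d", l + 1);
    arma::fmat Y(C_out, (size_t)L_out * B);
    arma::fmat col(C_in * p.K, L_out);
    for (int b = 0; b < B; ++b) {
      im2col(fc.A[l], b, L_in, p.K, p.stride, p.K / 2, col);
      Y.cols((size_t)b * L_out, (size_t)(b + 1) * L_out - 1) = p.W * col;
    }
    Y.each_col() += p.b;

    arma::fvec mu, va;
    if (use_batch[l]) {
      mu = arma::mean(Y, 1);
      arma::fvec m2 = arma::mean(arma::square(Y), 1);
      va = m2 - arma::square(mu);
      va.transform([](double v) { return v < 0 ? 0 : v; });
    } else {
      mu = p.rmean;
      va = p.rvar;
    }
    arma::fvec istd = 1.0 / arma::sqrt(va + BN_EPS);
    arma::fmat xh = Y;
    xh.each_col() -= mu;
    xh.each_col() %= istd;
    arma::fmat out = xh;
    out.each_col() %= p.gamma;
    out.each_col() += p.beta;
    out.transform([](double v) { return v > 0 ? v : 0; });  // ReLU

    fc.Ls[l + 1] = L_out;
    fc.A[l + 1] = std::move(out);
    if (keep_cache) {
      fc.xhat[l + 1] = std::move(xh);
      fc.invstd[l + 1] = istd;
      fc.bmean[l + 1] = mu;
      fc.bvar[l + 1] = va;
    }
  }

  // pooling over time -> C8 x B features
  const arma::fmat& Atop = fc.A[n_blocks];
  const int Ltop = fc.Ls[n_blocks];
  const int Ctop = Atop.n_rows;
  fc.feat.set_size(Ctop, B);
  if (pooling == 1) fc.argmax.set_size(Ctop, B);
  for (int b = 0; b < B; ++b) {
    arma::fmat blk = Atop.cols((size_t)b * Ltop, (size_t)(b + 1) * Ltop - 1);
    if (pooling == 0) {
      fc.feat.col(b) = arma::mean(blk, 1);
    } else {
      for (int c = 0; c < Ctop; ++c) {
        arma::uword idx;
        fc.feat(c, b) = blk.row(c).max(idx);
        fc.argmax(c, b) = idx;
      }
    }
  }
  fc.logits = fc.feat.t() * head_w + head_b;
  return fc;
}

// [[Rcpp::export]]
arma::fvec cnn_forward_cpp(List blocks, NumericVector head_w, double head_b,
                           NumericVector X, bool training, int pooling) {
  std::vector<BlockParams> bp = unpack_blocks(blocks);
  std::vector<bool> use_batch(bp.size(), training);
  ForwardCache fc = forward_pass(bp, fvec_from_r(head_w), head_b,
                                 cube_from_r(X), use_batch, pooling, false);
  return fc.logits;
}

// Loss + gradients for one minibatch. Blocks 1..n_frozen are frozen:
// their BN runs in evaluation mode (running statistics, no buffer
// updates) and no gradients are computed for or through-below them.
// [[Rcpp::export]]
List cnn_grad_cpp(List blocks, NumericVector head_w_, double head_b,
                  NumericVector X_, NumericVector y_, double pos_weight,
                  int n_frozen, int pooling) {
  std::vector<BlockParams> bp = unpack_blocks(blocks);
  const int n_blocks = bp.size();
  arma::fvec head_w = fvec_from_r(head_w_);
  arma::fvec y = fvec_from_r(y_);
  arma::fcube X = cube_from_r(X_);
  const int B = X.n_slices;
  std::vector<bool> use_batch(n_blocks);
  for (int l = 0; l < n_blocks; ++l) use_batch[l] = (l >= n_frozen);
  ForwardCache fc = forward_pass(bp, head_w, head_b, X, use_batch,
                                 pooling, true);

  // BCE with logits (optionally class-weighted), mean over batch
  arma::fvec z = fc.logits;
  arma::fvec p = 1.0 / (1.0 + arma::exp(-z));
  double loss = 0.0;
  arma::fvec dz(B);
  for (int i = 0; i < B; ++i) {
    const double zi = z[i], yi = y[i], pi = p[i];
    double li = std::max(zi, 0.0) - zi * yi +
      std::log1p(std::exp(-std::fabs(zi)));
    double w = yi > 0.5 ? pos_weight : 1.0;
    loss += w * li;
    dz[i] = (1.0 - yi) * pi - pos_weight * yi * (1.0 - pi);
  }
  loss /= B;
  dz /= B;

  // head
  arma::fvec d_head_w = fc.feat * dz;
  double d_head_b = arma::sum(dz);
  arma::fmat dfeat = head_w * dz.t();    // Ctop x B

  // pooling backward
  const int Ltop = fc.Ls[n_blocks];
  const int Ctop = fc.A[n_blocks].n_rows;
  arma::fmat dA(Ctop, (size_t)Ltop * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    if (pooling == 0) {
      for (int c = 0; c < Ctop; ++c) {
        double g = dfeat(c, b) / Ltop;
        for (int t = 0; t < Ltop; ++t) dA(c, (size_t)b * Ltop + t) = g;
      }
    } else {
      for (int c = 0; c < Ctop; ++c)
        dA(c, (size_t)b * Ltop + fc.argmax(c, b)) = dfeat(c, b);
    }
  }

  List gblocks(n_blocks);
  for (int l = n_blocks - 1; l >= n_frozen; --l) {
    const BlockParams& p = bp[l];
    const int L_out = fc.Ls[l + 1], L_in = fc.Ls[l];
    const size_t N = (size_t)L_out * B;
    const int C = dA.n_rows;
    const arma::fmat& xh = fc.xhat[l + 1];
    const arma::fvec& istd = fc.invstd[l + 1];
    // ReLU backward in place (mask from the post-ReLU activation)
    {
      float* pa = dA.memptr();
      const float* pm = fc.A[l + 1].memptr();
      const size_t n = dA.n_elem;
      for (size_t i = 0; i < n; ++i) if (pm[i] <= 0.0f) pa[i] = 0.0f;
    }
    // BN backward (batch statistics; frozen blocks never reach here),
    // fused into one pass over the matrix to avoid full-size temporaries
    arma::fvec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
    arma::fvec sum_dx(C, arma::fill::zeros), sum_dxx(C, arma::fill::zeros);
    {
      const float* pa = dA.memptr();
      const float* px = xh.memptr();
      for (size_t j = 0; j < N; ++j) {
        const size_t off = j * C;
        for (int c = 0; c < C; ++c) {
          const float g = pa[off + c], x = px[off + c];
          dgamma[c] += g * x;
          dbeta[c] += g;
          const float dxh = g * p.gamma[c];
          sum_dx[c] += dxh;
          sum_dxx[c] += dxh * x;
        }
      }
      float* pw = dA.memptr();
      for (size_t j = 0; j < N; ++j) {
        const size_t off = j * C;
        for (int c = 0; c < C; ++c) {
          const float dxh = pw[off + c] * p.gamma[c];
          pw[off + c] = (dxh * (float)N - sum_dx[c] -
                         px[off + c] * sum_dxx[c]) *
            (istd[c] / (float)N);
        }
      }
    }
    arma::fmat& dY = dA;                // dA now holds the conv-output grad
    // conv backward
    arma::fmat dWt(p.W.n_cols, p.W.n_rows, arma::fill::zeros);
    arma::fvec db = arma::sum(dY, 1);
    const bool need_dA = (l > n_frozen);
    arma::fmat dA_prev;
    if (need_dA)
      dA_prev.zeros(fc.A[l].n_rows, (size_t)L_in * B);
    const arma::fmat Wt = p.W.t();
    arma::fmat col(fc.A[l].n_rows * p.K, L_out);
    arma::fmat dYbt(L_out, p.W.n_rows);
    for (int b = 0; b < B; ++b) {
      im2col(fc.A[l], b, L_in, p.K, p.stride, p.K / 2, col);
      dYbt = dY.cols((size_t)b * L_out, (size_t)(b + 1) * L_out - 1).t();
      dWt += col * dYbt;
      if (need_dA) {
        arma::fmat dcol = Wt * dY.cols((size_t)b * L_out,
                                       (size_t)(b + 1) * L_out - 1);
        col2im(dcol, b, L_in, p.K, p.stride, p.K / 2, dA_prev);
      }
    }
    gblocks[l] = List::create(_["W"] = arma::fmat(dWt.t()), _["b"] = db,
                              _["gamma"] = dgamma, _["beta"] = dbeta);
    if (need_dA) dA = std::move(dA_prev);
  }

  // minibatch BN statistics for running-average updates (trainable blocks)
  List bmeans(n_blocks), bvars(n_blocks);
  for (int l = n_frozen; l < n_blocks; ++l) {
    bmeans[l] = fc.bmean[l + 1];
    bvars[l] = fc.bvar[l + 1];
  }

  return List::create(_["loss"] = loss, _["logits"] = z,
                      _["grads"] = gblocks,
                      _["head_w"] = d_head_w, _["head_b"] = d_head_b,
                      _["batch_mean"] = bmeans, _["batch_var"] = bvars);
}
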