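// Batched training of the fixed-topology precursor classifier:
//   input 1 x 7 x L -> conv(2x2, nf1) + ReLU -> maxpool 2x2
//                   -> conv(2x2, nf2) + ReLU -> maxpool 2x2
//                   -> flatten -> FC(fc, identity) -> FC(2) -> softmax,
// negative log likelihood loss, AdaDelta updates, inverted dropout
// (retain probability `retain`) on pool1 output, the flattened pool2
// output and the FC hidden layer, at training time only.
//
// Feature maps are stored as (channels x (height*width)) matrices with
// column index r + height*c; convolutions run as im2col + GEMM.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int L, nf1, nf2, fc;
  int h1, w1, hp1, wp1, m1, mp1;   // conv1 / pool1
  int h2, w2, wp2, m2;             // conv2 / pool2
  int flat;
};

Dims make_dims(int L, int nf1, int nf2, int fc) {
  Dims d;
  d.L = L; d.nf1 = nf1; d.nf2 = nf2; d.fc = fc;
  d.h1 = 6;       d.w1 = L - 1;
  d.hp1 = 3;      d.wp1 = d.w1 / 2;
  d.m1 = d.h1 * d.w1;   d.mp1 = d.hp1 * d.wp1;
  d.h2 = 2;       d.w2 = d.wp1 - 1;
  d.wp2 = d.w2 / 2;     d.m2 = d.h2 * d.w2;
  d.flat = nf2 * d.wp2;
  if (d.w1 < 2 || d.w2 < 2 || d.wp2 < 1)
    Rcpp::stop("input width %d is too small for the layer stack", L);
  return d;
}

struct Weights {
  mat W1, W2, W3, W4;
  vec b1, b2, b3, b4;
};

Weights read_weights(const Rcpp::List& w) {
  Weights W;
  W.W1 = Rcpp::as<mat>(w["W1"]); W.b1 = Rcpp::as<vec>(w["b1"]);
  W.W2 = Rcpp::as<mat>(w["W2"]); W.b2 = Rcpp::as<vec>(w["b2"]);
  W.W3 = Rcpp::as<mat>(w["W3"]); W.b3 = Rcpp::as<vec>(w["b3"]);
  W.W4 = Rcpp::as<mat>(w["W4"]); W.b4 = Rcpp::as<vec>(w["b4"]);
  return W;
}

// column-major im2col of one 7 x L sample into 4 x m1 patch columns
void im2col1(const mat& x, int b, const Dims& d, mat& P1) {
  for (int c = 0; c < d.w1; ++c)
    for (int r = 0; r < d.h1; ++r) {
      int col = b * d.m1 + r + d.h1 * c;
      P1(0, col) = x(r, c);
      P1(1, col) = x(r + 1, c);
      P1(2, col) = x(r, c + 1);
      P1(3, col) = x(r + 1, c + 1);
    }
}

// 2x2/stride-2 max pooling of (nch x (h*w)) blocks with argmax bookkeeping
void pool2x2(const mat& A, int nch, int h, int w, int hp, int wp, int B,
             mat& out, umat& amax) {
  const int m = h * w, mp = hp * wp;
  for (int b = 0; b < B; ++b)
    for (int cc = 0; cc < wp; ++cc)
      for (int rr = 0; rr < hp; ++rr) {
        int oc = b * mp + rr + hp * cc;
        uword i0 = b * m + 2 * rr + h * (2 * cc);
        uword cand[4] = { i0, i0 + 1, i0 + (uword)h, i0 + (uword)h + 1 };
        for (int ch = 0; ch < nch; ++ch) {
          double best = A(ch, cand[0]); uword bi = cand[0];
          for (int q = 1; q < 4; ++q)
            if (A(ch, cand[q]) > best) { best = A(ch, cand[q]); bi = cand[q]; }
          out(ch, oc) = best;
          amax(ch, oc) = bi;
        }
      }
}

// gather pooled conv1 channels into conv2 patch columns (80 x m2 per sample)
void im2col2(const mat& D1, int b, const Dims& d, mat& P2) {
  const int nf1 = d.nf1;
  for (int c = 0; c < d.w2; ++c)
    for (int r = 0; r < d.h2; ++r) {
      double* dst = P2.colptr(b * d.m2 + r + d.h2 * c);
      for (int dc = 0; dc < 2; ++dc)
        for (int dr = 0; dr < 2; ++dr) {
          const double* src = D1.colptr(b * d.mp1 + (r + dr) +
                                        d.hp1 * (c + dc));
          std::copy(src, src + nf1, dst + nf1 * (dr + 2 * dc));
        }
    }
}

void softmax_cols(mat& O) {
  rowvec mx = max(O, 0);
  O.each_row() -= mx;
  O = exp(O);
  rowvec s = sum(O, 0);
  O.each_row() /= s;
}

void adadelta_step(mat& W, const mat& g, mat& Eg, mat& Ed,
                   double rho, double eps) {
  Eg = rho * Eg + (1.0 - rho) * square(g);
  mat dx = -sqrt(Ed + eps) / sqrt(Eg + eps) % g;
  Ed = rho * Ed + (1.0 - rho) * square(dx);
  W += dx;
}

void adadelta_step(vec& W, const vec& g, vec& Eg, vec& Ed,
                   double rho, double eps) {
  Eg = rho * Eg + (1.0 - rho) * square(g);
  vec dx = -sqrt(Ed + eps) / sqrt(Eg + eps) % g;
  Ed = rho * Ed + (1.0 - rho) * square(dx);
  W += dx;
}

mat dropout_mask(int nr, int nc, double retain, std::mt19937_64& rng) {
  mat M(nr, nc);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const double inv = 1.0 / retain;
  for (uword j = 0; j < (uword)nc; ++j)
    for (uword i = 0; i < (uword)nr; ++i)
      M(i, j) = (U(rng) < retain) ? inv : 0.0;
  return M;
}

} // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::cube& X, const arma::ivec& y,
                         arma::uvec idx, const Rcpp::List& w0,
                         int epochs, int batch, double retain,
                         double rho, double eps, int seed) {
  Weights W = read_weights(w0);
  const int L = (int) X.n_cols;
  Dims d = make_dims(L, (int) W.W1.n_rows, (int) W.W2.n_rows,
                     (int) W.W3.n_rows);
  if ((int) W.W2.n_cols != 4 * d.nf1 || (int) W.W3.n_cols != d.flat)
    Rcpp::stop("weight shapes do not match the input width");

  Weights Eg, Ed;  // AdaDelta accumulators
  Eg.W1.zeros(size(W.W1)); Ed.W1.zeros(size(W.W1));
  Eg.W2.zeros(size(W.W2)); Ed.W2.zeros(size(W.W2));
  Eg.W3.zeros(size(W.W3)); Ed.W3.zeros(size(W.W3));
  Eg.W4.zeros(size(W.W4)); Ed.W4.zeros(size(W.W4));
  Eg.b1.zeros(size(W.b1)); Ed.b1.zeros(size(W.b1));
  Eg.b2.zeros(size(W.b2)); Ed.b2.zeros(size(W.b2));
  Eg.b3.zeros(size(W.b3)); Ed.b3.zeros(size(W.b3));
  Eg.b4.zeros(size(W.b4)); Ed.b4.zeros(size(W.b4));

  std::mt19937_64 rng((uint64_t) seed);
  const bool drop = retain < 1.0;
  std::vector<double> epoch_loss(epochs, 0.0);
  const int ntr = (int) idx.n_elem;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0.0;
    for (int off = 0; off < ntr; off += batch) {
      const int B = std::min(batch, ntr - off);

      mat P1(4, d.m1 * B);
      for (int b = 0; b < B; ++b)
        im2col1(X.slice(idx[off + b]), b, d, P1);

      mat A1 = W.W1 * P1;            // conv1 + ReLU
      A1.each_col() += W.b1;
      A1.for_each([](double& v) { if (v < 0) v = 0; });

      mat Q1(d.nf1, d.mp1 * B); umat am1(d.nf1, d.mp1 * B);
      pool2x2(A1, d.nf1, d.h1, d.w1, d.hp1, d.wp1, B, Q1, am1);

      mat M1; mat D1;
      if (drop) { M1 = dropout_mask(d.nf1, d.mp1 * B, retain, rng); D1 = Q1 % M1; }
      else D1 = Q1;

      mat P2(4 * d.nf1, d.m2 * B);
      for (int b = 0; b < B; ++b) im2col2(D1, b, d, P2);

      mat A2 = W.W2 * P2;            // conv2 + ReLU
      A2.each_col() += W.b2;
      A2.for_each([](double& v) { if (v < 0) v = 0; });

      mat Q2(d.nf2, d.wp2 * B); umat am2(d.nf2, d.wp2 * B);
      pool2x2(A2, d.nf2, d.h2, d.w2, 1, d.wp2, B, Q2, am2);

      mat F(d.flat, B);
      for (int b = 0; b < B; ++b)
        F.col(b) = vectorise(Q2.cols(b * d.wp2, (b + 1) * d.wp2 - 1));

      mat Mf; mat Df;
      if (drop) { Mf = dropout_mask(d.flat, B, retain, rng); Df = F % Mf; }
      else Df = F;

      mat H = W.W3 * Df;             // FC, identity activation
      H.each_col() += W.b3;
      mat Mh; mat Dh;
      if (drop) { Mh = dropout_mask(d.fc, B, retain, rng); Dh = H % Mh; }
      else Dh = H;

      mat O = W.W4 * Dh;             // output + softmax
      O.each_col() += W.b4;
      softmax_cols(O);

      double nll = 0.0;
      for (int b = 0; b < B; ++b)
        nll -= std::log(std::max(O(y[idx[off + b]], b), 1e-300));
      loss_sum += nll;

      // ---- backward ----
      mat G4 = O;
      for (int b = 0; b < B; ++b) G4(y[idx[off + b]], b) -= 1.0;
      G4 /= (double) B;

      mat dW4 = G4 * Dh.t();  vec db4 = sum(G4, 1);
      mat dH = W.W4.t() * G4; if (drop) dH %= Mh;
      mat dW3 = dH * Df.t();  vec db3 = sum(dH, 1);
      mat dF = W.W3.t() * dH; if (drop) dF %= Mf;

      mat dQ2(d.nf2, d.wp2 * B);
      for (int b = 0; b < B; ++b)
        dQ2.cols(b * d.wp2, (b + 1) * d.wp2 - 1) =
          reshape(dF.col(b), d.nf2, d.wp2);

      mat dA2(d.nf2, d.m2 * B, fill::zeros);
      for (uword j = 0; j < dQ2.n_cols; ++j)
        for (int ch = 0; ch < d.nf2; ++ch)
          dA2(ch, am2(ch, j)) += dQ2(ch, j);
      dA2 %= conv_to<mat>::from(A2 > 0);

      mat dW2 = dA2 * P2.t(); vec db2 = sum(dA2, 1);
      mat dP2 = W.W2.t() * dA2;

      mat dD1(d.nf1, d.mp1 * B, fill::zeros);   // col2im accumulate
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < d.w2; ++c)
          for (int r = 0; r < d.h2; ++r) {
            const double* src0 = dP2.colptr(b * d.m2 + r + d.h2 * c);
            for (int dc = 0; dc < 2; ++dc)
              for (int dr = 0; dr < 2; ++dr) {
                double* dst = dD1.colptr(b * d.mp1 + (r + dr) +
                                         d.hp1 * (c + dc));
                const double* src = src0 + d.nf1 * (dr + 2 * dc);
                for (int ch = 0; ch < d.nf1; ++ch) dst[ch] += src[ch];
              }
          }
      if (drop) dD1 %= M1;

      mat dA1(d.nf1, d.m1 * B, fill::zeros);
      for (uword j = 0; j < dD1.n_cols; ++j)
        for (int ch = 0; ch < d.nf1; ++ch)
          dA1(ch, am1(ch, j)) += dD1(ch, j);
      dA1 %= conv_to<mat>::from(A1 > 0);

      mat dW1 = dA1 * P1.t(); vec db1 = sum(dA1, 1);

      adadelta_step(W.W1, dW1, Eg.W1, Ed.W1, rho, eps);
      adadelta_step(W.b1, db1, Eg.b1, Ed.b1, rho, eps);
      adadelta_step(W.W2, dW2, Eg.W2, Ed.W2, rho, eps);
      adadelta_step(W.b2, db2, Eg.b2, Ed.b2, rho, eps);
      adadelta_step(W.W3, dW3, Eg.W3, Ed.W3, rho, eps);
      adadelta_step(W.b3, db3, Eg.b3, Ed.b3, rho, eps);
      adadelta_step(W.W4, dW4, Eg.W4, Ed.W4, rho, eps);
      adadelta_step(W.b4, db4, Eg.b4, Ed.b4, rho, eps);
    }
    epoch_loss[ep] = loss_sum / ntr;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::_["weights"] = Rcpp::List::create(
      Rcpp::_["W1"] = W.W1, Rcpp::_["b1"] = W.b1,
      Rcpp::_["W2"] = W.W2, Rcpp::_["b2"] = W.b2,
      Rcpp::_["W3"] = W.W3, Rcpp::_["b3"] = W.b3,
      Rcpp::_["W4"] = W.W4, Rcpp::_["b4"] = W.b4),
    Rcpp::_["epoch_loss"] = epoch_loss);
}

// Inference-mode forward pass (no dropout); returns N x 2 softmax matrix.
// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(const arma::cube& X, const Rcpp::List& w0) {
  Weights W = read_weights(w0);
  const int L = (int) X.n_cols, N = (int) X.n_slices;
  Dims d = make_dims(L, (int) W.W1.n_rows, (int) W.W2.n_rows,
                     (int) W.W3.n_rows);
  mat out(N, 2);
  const int batch = 256;
  for (int off = 0; off < N; off += batch) {
    const int B = std::min(batch, N - off);
    mat P1(4, d.m1 * B);
    for (int b = 0; b < B; ++b) im2col1(X.slice(off + b), b, d, P1);
    mat A1 = W.W1 * P1; A1.each_col() += W.b1;
    A1.for_each([](double& v) { if (v < 0) v = 0; });
    mat Q1(d.nf1, d.mp1 * B); umat am1(d.nf1, d.mp1 * B);
    pool2x2(A1, d.nf1, d.h1, d.w1, d.hp1, d.wp1, B, Q1, am1);
    mat P2(4 * d.nf1, d.m2 * B);
    for (int b = 0; b < B; ++b) im2col2(Q1, b, d, P2);
    mat A2 = W.W2 * P2; A2.each_col() += W.b2;
    A2.for_each([](double& v) { if (v < 0) v = 0; });
    mat Q2(d.nf2, d.wp2 * B); umat am2(d.nf2, d.wp2 * B);
    pool2x2(A2, d.nf2, d.h2, d.w2, 1, d.wp2, B, Q2, am2);
    mat F(d.flat, B);
    for (int b = 0; b < B; ++b)
      F.col(b) = vectorise(Q2.cols(b * d.wp2, (b + 1) * d.wp2 - 1));
    mat H = W.W3 * F; H.each_col() += W.b3;
    mat O = W.W4 * H; O.each_col() += W.b4;
    softmax_cols(O);
    out.rows(off, off + B - 1) = O.t();
  }
  return out;
}
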