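// Small convolutional network over 129x124 standardized spectrogram inputs:
// conv(3x3,16) -> relu -> maxpool2 -> conv(3x3,32) -> relu -> maxpool2 ->
// flatten -> dropout -> dense(64) -> relu -> softmax(K).
// Convolutions run as im2col + GEMM; training is plain seeded Adam on the
// softmax cross-entropy. Everything is deterministic given the seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using namespace arma;

namespace {

struct Dims {
  int H, W;              // input
  int C1, C2, Hd, K;     // channel/unit counts
  int H1, W1, Q1h, Q1w;  // conv1 out, pool1 out
  int H2, W2, Q2h, Q2w;  // conv2 out, pool2 out
  int F;                 // flattened features
};

struct Weights {
  mat W1, W2, Wd, Wo;
  rowvec b1, b2, bd, bo;
};

Weights unpack(const List& w) {
  Weights wt;
  wt.W1 = as<mat>(w["W1"]); wt.b1 = as<rowvec>(w["b1"]);
  wt.W2 = as<mat>(w["W2"]); wt.b2 = as<rowvec>(w["b2"]);
  wt.Wd = as<mat>(w["Wd"]); wt.bd = as<rowvec>(w["bd"]);
  wt.Wo = as<mat>(w["Wo"]); wt.bo = as<rowvec>(w["bo"]);
  return wt;
}

List pack(const Weights& wt) {
  return List::create(
    Named("W1") = wt.W1, Named("b1") = wt.b1,
    Named("W2") = wt.W2, Named("b2") = wt.b2,
    Named("Wd") = wt.Wd, Named("bd") = wt.bd,
    Named("Wo") = wt.Wo, Named("bo") = wt.bo);
}

Dims make_dims(const Weights& wt, int H, int W) {
  Dims d;
  d.H = H; d.W = W;
  d.C1 = wt.W1.n_cols; d.C2 = wt.W2.n_cols;
  d.Hd = wt.Wd.n_cols; d.K = wt.Wo.n_cols;
  if ((int)wt.W1.n_rows != 9 || (int)wt.W2.n_rows != 9 * d.C1)
    stop("weight shapes inconsistent with a 3x3 two-stage conv stack");
  d.H1 = H - 2; d.W1 = W - 2;
  d.Q1h = d.H1 / 2; d.Q1w = d.W1 / 2;
  d.H2 = d.Q1h - 2; d.W2 = d.Q1w - 2;
  d.Q2h = d.H2 / 2; d.Q2w = d.W2 / 2;
  d.F = d.Q2h * d.Q2w * d.C2;
  if ((int)wt.Wd.n_rows != d.F)
    stop("dense weight rows (%d) do not match flattened size (%d)",
         (int)wt.Wd.n_rows, d.F);
  return d;
}

// im2col over a single-channel image, valid 3x3; P is (H1*W1) x 9.
void im2col_1(const mat& x, int H1, int W1, mat& P) {
  for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di)
      P.col(di + 3 * dj) =
        vectorise(x.submat(di, dj, di + H1 - 1, dj + W1 - 1));
}

// im2col over a C-channel activation stored as (Ph*Pw) x C (column-major
// spatial layout per channel); P is (H2*W2) x (9*C), column c*9 + di + 3*dj.
void im2col_C(const mat& A, int Ph, int Pw, mat& P) {
  const int H2 = Ph - 2, W2 = Pw - 2, C = A.n_cols;
  for (int c = 0; c < C; ++c) {
    const mat ch(const_cast<double*>(A.colptr(c)), Ph, Pw, false, true);
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di)
        P.col(c * 9 + di + 3 * dj) =
          vectorise(ch.submat(di, dj, di + H2 - 1, dj + W2 - 1));
  }
}

// Scatter-add of the im2col gradient back onto the activation grid.
void col2im_C(const mat& dP, int Ph, int Pw, mat& dA) {
  const int H2 = Ph - 2, W2 = Pw - 2, C = dA.n_cols;
  dA.zeros();
  for (int c = 0; c < C; ++c) {
    mat ch(dA.colptr(c), Ph, Pw, false, true);
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di)
        ch.submat(di, dj, di + H2 - 1, dj + W2 - 1) +=
          reshape(dP.col(c * 9 + di + 3 * dj), H2, W2);
  }
}

// 2x2/stride-2 max pool with argmax bookkeeping (row index into A).
void maxpool2(const mat& A, int Ph, int Pw, mat& out, umat& amax) {
  const int Qh = Ph / 2, Qw = Pw / 2, C = A.n_cols;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Qw; ++j)
      for (int i = 0; i < Qh; ++i) {
        double best = -datum::inf;
        uword bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            uword idx = (2 * i + di) + (uword)(2 * j + dj) * Ph;
            double v = A(idx, c);
            if (v > best) { best = v; bidx = idx; }
          }
        out(i + j * Qh, c) = best;
        amax(i + j * Qh, c) = bidx;
      }
}

struct Cache {
  mat P1, A1, Q1, P2, A2, Q2;
  umat amax1, amax2;
  rowvec flat, h;
  rowvec drop;  // dropout multiplier on flat (1/(1-p) or 0)
};

void alloc_cache(const Dims& d, Cache& c) {
  c.P1.set_size(d.H1 * d.W1, 9);
  c.A1.set_size(d.H1 * d.W1, d.C1);
  c.Q1.set_size(d.Q1h * d.Q1w, d.C1);
  c.amax1.set_size(d.Q1h * d.Q1w, d.C1);
  c.P2.set_size(d.H2 * d.W2, 9 * d.C1);
  c.A2.set_size(d.H2 * d.W2, d.C2);
  c.Q2.set_size(d.Q2h * d.Q2w, d.C2);
  c.amax2.set_size(d.Q2h * d.Q2w, d.C2);
}

rowvec forward_sample(const mat& x, const Weights& wt, const Dims& d,
                      Cache& c, bool use_dropout) {
  im2col_1(x, d.H1, d.W1, c.P1);
  c.A1 = c.P1 * wt.W1;
  c.A1.each_row() += wt.b1;
  c.A1.transform([](double v) { return v > 0 ? v : 0.0; });
  maxpool2(c.A1, d.H1, d.W1, c.Q1, c.amax1);
  im2col_C(c.Q1, d.Q1h, d.Q1w, c.P2);
  c.A2 = c.P2 * wt.W2;
  c.A2.each_row() += wt.b2;
  c.A2.transform([](double v) { return v > 0 ? v : 0.0; });
  maxpool2(c.A2, d.H2, d.W2, c.Q2, c.amax2);
  c.flat = vectorise(c.Q2).t();
  if (use_dropout) c.flat %= c.drop;
  c.h = c.flat * wt.Wd + wt.bd;
  c.h.transform([](double v) { return v > 0 ? v : 0.0; });
  rowvec logits = c.h * wt.Wo + wt.bo;
  logits -= logits.max();
  rowvec p = exp(logits);
  return p / accu(p);
}

void backward_sample(const mat& /*x*/, const rowvec& p, int y,
                     const Weights& wt, const Dims& d, Cache& c,
                     bool use_dropout, Weights& g) {
  rowvec dlogit = p;
  dlogit(y) -= 1.0;
  g.Wo += c.h.t() * dlogit;
  g.bo += dlogit;
  rowvec dh = dlogit * wt.Wo.t();
  for (int i = 0; i < d.Hd; ++i) if (c.h(i) <= 0) dh(i) = 0;
  g.Wd += c.flat.t() * dh;
  g.bd += dh;
  rowvec dflat = dh * wt.Wd.t();
  if (use_dropout) dflat %= c.drop;
  mat dQ2(dflat.memptr(), d.Q2h * d.Q2w, d.C2, false, true);
  mat dA2(d.H2 * d.W2, d.C2, fill::zeros);
  for (int cc = 0; cc < d.C2; ++cc)
    for (uword k = 0; k < dQ2.n_rows; ++k)
      dA2(c.amax2(k, cc), cc) += dQ2(k, cc);
  for (uword i = 0; i < dA2.n_elem; ++i) if (c.A2(i) <= 0) dA2(i) = 0;
  g.W2 += c.P2.t() * dA2;
  g.b2 += sum(dA2, 0);
  mat dP2 = dA2 * wt.W2.t();
  mat dQ1(d.Q1h * d.Q1w, d.C1);
  col2im_C(dP2, d.Q1h, d.Q1w, dQ1);
  mat dA1(d.H1 * d.W1, d.C1, fill::zeros);
  for (int cc = 0; cc < d.C1; ++cc)
    for (uword k = 0; k < dQ1.n_rows; ++k)
      dA1(c.amax1(k, cc), cc) += dQ1(k, cc);
  for (uword i = 0; i < dA1.n_elem; ++i) if (c.A1(i) <= 0) dA1(i) = 0;
  g.W1 += c.P1.t() * dA1;
  g.b1 += sum(dA1, 0);
}

struct Adam {
  mat mW1, vW1, mW2, vW2, mWd, vWd, mWo, vWo;
  rowvec mb1, vb1, mb2, vb2, mbd, vbd, mbo, vbo;
  long t = 0;
  void init(const Weights& w) {
    mW1 = zeros(size(w.W1)); vW1 = mW1;
    mW2 = zeros(size(w.W2)); vW2 = mW2;
    mWd = zeros(size(w.Wd)); vWd = mWd;
    mWo = zeros(size(w.Wo)); vWo = mWo;
    mb1 = zeros<rowvec>(w.b1.n_elem); vb1 = mb1;
    mb2 = zeros<rowvec>(w.b2.n_elem); vb2 = mb2;
    mbd = zeros<rowvec>(w.bd.n_elem); vbd = mbd;
    mbo = zeros<rowvec>(w.bo.n_elem); vbo = mbo;
  }
  template <typename T>
  void upd(T& w, const T& g, T& m, T& v, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    T mh = m / (1 - std::pow(b1, (double)t));
    T vh = v / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void step(Weights& w, const Weights& g, double lr) {
    ++t;
    upd(w.W1, g.W1, mW1, vW1, lr); upd(w.b1, g.b1, mb1, vb1, lr);
    upd(w.W2, g.W2, mW2, vW2, lr); upd(w.b2, g.b2, mb2, vb2, lr);
    upd(w.Wd, g.Wd, mWd, vWd, lr); upd(w.bd, g.bd, mbd, vbd, lr);
    upd(w.Wo, g.Wo, mWo, vWo, lr); upd(w.bo, g.bo, mbo, vbo, lr);
  }
};

void zero_like(const Weights& w, Weights& g) {
  g.W1 = zeros(size(w.W1)); g.b1 = zeros<rowvec>(w.b1.n_elem);
  g.W2 = zeros(size(w.W2)); g.b2 = zeros<rowvec>(w.b2.n_elem);
  g.Wd = zeros(size(w.Wd)); g.bd = zeros<rowvec>(w.bd.n_elem);
  g.Wo = zeros(size(w.Wo)); g.bo = zeros<rowvec>(w.bo.n_elem);
}

void scale_grads(Weights& g, double s) {
  g.W1 *= s; g.b1 *= s; g.W2 *= s; g.b2 *= s;
  g.Wd *= s; g.bd *= s; g.Wo *= s; g.bo *= s;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(List weights, const arma::cube& X) {
  Weights wt = unpack(weights);
  Dims d = make_dims(wt, X.n_rows, X.n_cols);
  Cache c;
  alloc_cache(d, c);
  mat out(X.n_slices, d.K);
  for (uword i = 0; i < X.n_slices; ++i)
    out.row(i) = forward_sample(X.slice(i), wt, d, c, false);
  return out;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(List weights, const arma::cube& X, const arma::ivec& y,
                   const arma::cube& Xval, const arma::ivec& yval,
                   int epochs, int batch, double lr, double dropout,
                   int seed, bool verbose) {
  Weights wt = unpack(weights);
  Dims d = make_dims(wt, X.n_rows, X.n_cols);
  const int n = X.n_slices;
  if ((int)y.n_elem != n) stop("label count does not match input count");
  Cache c;
  alloc_cache(d, c);
  c.drop.set_size(d.F);
  Weights g;
  Adam adam;
  adam.init(wt);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  vec train_loss(epochs, fill::zeros);
  vec val_acc(epochs, fill::value(datum::nan));

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0;
    for (int start = 0; start < n; start += batch) {
      int bend = std::min(start + batch, n);
      zero_like(wt, g);
      for (int b = start; b < bend; ++b) {
        const mat& x = X.slice(idx[b]);
        if (dropout > 0) {
          for (int f = 0; f < d.F; ++f)
            c.drop(f) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        } else {
          c.drop.ones();
        }
        rowvec p = forward_sample(x, wt, d, c, dropout > 0);
        int yy = y(idx[b]);
        loss_sum += -std::log(std::max(p(yy), 1e-12));
        backward_sample(x, p, yy, wt, d, c, dropout > 0, g);
      }
      scale_grads(g, 1.0 / (bend - start));
      adam.step(wt, g, lr);
      Rcpp::checkUserInterrupt();
    }
    train_loss(ep) = loss_sum / n;
    if (Xval.n_slices > 0 && Xval.n_elem > 1) {
      int correct = 0;
      for (uword i = 0; i < Xval.n_slices; ++i) {
        rowvec p = forward_sample(Xval.slice(i), wt, d, c, false);
        if ((int)p.index_max() == (int)yval(i)) ++correct;
      }
      val_acc(ep) = (double)correct / Xval.n_slices;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << ": loss " << train_loss(ep)
                  << ", val acc " << val_acc(ep) << "\n";
  }
  return List::create(Named("weights") = pack(wt),
                      Named("train_loss") = train_loss,
                      Named("val_accuracy") = val_acc);
}
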