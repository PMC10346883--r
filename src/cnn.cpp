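// Compact 1-D convolutional network over per-axis spectral magnitudes.
//
// Architecture (fixed topology, sizes configurable from R):
//   conv1d -> ReLU -> maxpool -> dropout ->
//   conv1d -> ReLU -> maxpool -> dropout ->
//   flatten -> dense ReLU -> dropout -> dense softmax
// trained with categorical cross-entropy and RMSprop.
//
// All randomness (weight init, shuffling, dropout) comes from R's RNG, so
// set.seed() on the R side makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Arch {
  int M, Cin, f1, k1, p1, f2, k2, p2, d1, C;
  double dr1, dr2, dr3;
  int L1, L1p, L2, L2p, flat;
};

Arch parse_arch(const List& a) {
  Arch r;
  r.M = as<int>(a["M"]);
  r.Cin = as<int>(a["n_axes"]);
  r.f1 = as<int>(a["conv1_filters"]);
  r.k1 = as<int>(a["conv1_kernel"]);
  r.p1 = as<int>(a["pool1"]);
  r.f2 = as<int>(a["conv2_filters"]);
  r.k2 = as<int>(a["conv2_kernel"]);
  r.p2 = as<int>(a["pool2"]);
  r.d1 = as<int>(a["dense"]);
  r.C = as<int>(a["C"]);
  NumericVector dr = a["dropout"];
  r.dr1 = dr[0]; r.dr2 = dr[1]; r.dr3 = dr[2];
  r.L1 = r.M - r.k1 + 1;
  r.L1p = r.L1 / r.p1;
  r.L2 = r.L1p - r.k2 + 1;
  r.L2p = r.L2 / r.p2;
  r.flat = r.L2p * r.f2;
  if (r.L1 < 1 || r.L1p < 1 || r.L2 < 1 || r.L2p < 1)
    stop("spectrum length M too small for the configured kernels/pooling");
  return r;
}

struct Weights {
  arma::mat W1, W2, W3, W4;
  arma::rowvec b1, b2, b3, b4;
};

Weights weights_from_list(const List& w) {
  Weights r;
  r.W1 = as<arma::mat>(w["W1"]); r.b1 = as<arma::rowvec>(w["b1"]);
  r.W2 = as<arma::mat>(w["W2"]); r.b2 = as<arma::rowvec>(w["b2"]);
  r.W3 = as<arma::mat>(w["W3"]); r.b3 = as<arma::rowvec>(w["b3"]);
  r.W4 = as<arma::mat>(w["W4"]); r.b4 = as<arma::rowvec>(w["b4"]);
  return r;
}

List weights_to_list(const Weights& w) {
  return List::create(_["W1"] = w.W1, _["b1"] = w.b1,
                      _["W2"] = w.W2, _["b2"] = w.b2,
                      _["W3"] = w.W3, _["b3"] = w.b3,
                      _["W4"] = w.W4, _["b4"] = w.b4);
}

void relu_inplace(arma::mat& m) {
  m.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// X: B x (Cin*M), axis-major columns.  out: (B*L1) x (k1*Cin).
void im2col1(const arma::mat& X, const Arch& A, arma::mat& out) {
  const int B = X.n_rows;
  out.set_size((size_t)B * A.L1, (size_t)A.k1 * A.Cin);
  for (int c = 0; c < A.Cin; ++c)
    for (int j = 0; j < A.k1; ++j) {
      const int col = c * A.k1 + j;
      for (int b = 0; b < B; ++b) {
        const size_t ro = (size_t)b * A.L1;
        for (int t = 0; t < A.L1; ++t)
          out(ro + t, col) = X(b, c * A.M + t + j);
      }
    }
}

// P1: (B*L1p) x f1 pooled conv1 activations.  out: (B*L2) x (k2*f1).
void im2col2(const arma::mat& P1, const Arch& A, int B, arma::mat& out) {
  out.set_size((size_t)B * A.L2, (size_t)A.k2 * A.f1);
  for (int c = 0; c < A.f1; ++c)
    for (int j = 0; j < A.k2; ++j) {
      const int col = c * A.k2 + j;
      for (int b = 0; b < B; ++b) {
        const size_t ro = (size_t)b * A.L2, ri = (size_t)b * A.L1p + j;
        for (int t = 0; t < A.L2; ++t)
          out(ro + t, col) = P1(ri + t, c);
      }
    }
}

void maxpool(const arma::mat& Ain, int B, int Lin, int p, int Lout,
             arma::mat& P, arma::umat& idx) {
  const int F = Ain.n_cols;
  P.set_size((size_t)B * Lout, F);
  idx.set_size((size_t)B * Lout, F);
  for (int f = 0; f < F; ++f)
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Lout; ++t) {
        const size_t base = (size_t)b * Lin + (size_t)t * p;
        double best = Ain(base, f);
        size_t bi = base;
        for (int q = 1; q < p; ++q) {
          const double v = Ain(base + q, f);
          if (v > best) { best = v; bi = base + q; }
        }
        P((size_t)b * Lout + t, f) = best;
        idx((size_t)b * Lout + t, f) = bi;
      }
}

void flatten(const arma::mat& P2, const Arch& A, int B, arma::mat& F) {
  F.set_size(B, A.flat);
  for (int b = 0; b < B; ++b) {
    const size_t ri = (size_t)b * A.L2p;
    for (int t = 0; t < A.L2p; ++t)
      for (int c = 0; c < A.f2; ++c)
        F(b, t * A.f2 + c) = P2(ri + t, c);
  }
}

arma::mat dropout_mask(size_t r, size_t c, double p) {
  arma::mat m(r, c);
  const double keep = 1.0 - p;
  for (size_t i = 0; i < m.n_elem; ++i)
    m(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

struct Cache {
  arma::mat Xc1, A1, P1, Xc2, A2, P2, F, A3;
  arma::umat idx1, idx2;
  arma::mat m1, m2, m3;
};

// Forward pass.  If y != nullptr the (class-weighted) mean cross-entropy
// is returned; probs always receives the softmax output.
double forward(const Weights& W, const Arch& A, const arma::mat& X,
               const arma::ivec* y, const arma::vec* cw, bool training,
               Cache& C, arma::mat& probs) {
  const int B = X.n_rows;
  im2col1(X, A, C.Xc1);
  C.A1 = C.Xc1 * W.W1;
  C.A1.each_row() += W.b1;
  relu_inplace(C.A1);
  maxpool(C.A1, B, A.L1, A.p1, A.L1p, C.P1, C.idx1);
  if (training && A.dr1 > 0) {
    C.m1 = dropout_mask(C.P1.n_rows, C.P1.n_cols, A.dr1);
    C.P1 %= C.m1;
  } else C.m1.reset();
  im2col2(C.P1, A, B, C.Xc2);
  C.A2 = C.Xc2 * W.W2;
  C.A2.each_row() += W.b2;
  relu_inplace(C.A2);
  maxpool(C.A2, B, A.L2, A.p2, A.L2p, C.P2, C.idx2);
  if (training && A.dr2 > 0) {
    C.m2 = dropout_mask(C.P2.n_rows, C.P2.n_cols, A.dr2);
    C.P2 %= C.m2;
  } else C.m2.reset();
  flatten(C.P2, A, B, C.F);
  C.A3 = C.F * W.W3;
  C.A3.each_row() += W.b3;
  relu_inplace(C.A3);
  if (training && A.dr3 > 0) {
    C.m3 = dropout_mask(C.A3.n_rows, C.A3.n_cols, A.dr3);
    C.A3 %= C.m3;
  } else C.m3.reset();
  arma::mat Z4 = C.A3 * W.W4;
  Z4.each_row() += W.b4;
  Z4.each_col() -= arma::max(Z4, 1);
  probs = arma::exp(Z4);
  probs.each_col() /= arma::sum(probs, 1);
  if (!y) return NA_REAL;
  double loss = 0.0, wsum = 0.0;
  for (int b = 0; b < B; ++b) {
    const double w = cw ? (*cw)((*y)(b)) : 1.0;
    loss -= w * std::log(std::max(probs(b, (*y)(b)), 1e-12));
    wsum += w;
  }
  return loss / wsum;
}

void backward(const Weights& W, const Arch& A, const Cache& C,
              const arma::mat& probs, const arma::ivec& y,
              const arma::vec* cw, Weights& G) {
  const int B = probs.n_rows;
  arma::mat dZ4 = probs;
  arma::vec wv(B);
  double wsum = 0.0;
  for (int b = 0; b < B; ++b) {
    wv(b) = cw ? (*cw)(y(b)) : 1.0;
    wsum += wv(b);
    dZ4(b, y(b)) -= 1.0;
  }
  dZ4.each_col() %= wv;
  dZ4 /= wsum;

  G.W4 = C.A3.t() * dZ4;
  G.b4 = arma::sum(dZ4, 0);
  arma::mat dA3 = dZ4 * W.W4.t();
  if (C.m3.n_elem) dA3 %= C.m3;
  dA3 %= arma::conv_to<arma::mat>::from(C.A3 > 0);

  G.W3 = C.F.t() * dA3;
  G.b3 = arma::sum(dA3, 0);
  arma::mat dF = dA3 * W.W3.t();

  arma::mat dP2((size_t)B * A.L2p, A.f2);
  for (int b = 0; b < B; ++b) {
    const size_t ro = (size_t)b * A.L2p;
    for (int t = 0; t < A.L2p; ++t)
      for (int c = 0; c < A.f2; ++c)
        dP2(ro + t, c) = dF(b, t * A.f2 + c);
  }
  if (C.m2.n_elem) dP2 %= C.m2;
  arma::mat dA2((size_t)B * A.L2, A.f2, arma::fill::zeros);
  for (size_t c = 0; c < dP2.n_cols; ++c)
    for (size_t r = 0; r < dP2.n_rows; ++r)
      dA2(C.idx2(r, c), c) += dP2(r, c);
  dA2 %= arma::conv_to<arma::mat>::from(C.A2 > 0);

  G.W2 = C.Xc2.t() * dA2;
  G.b2 = arma::sum(dA2, 0);
  arma::mat dXc2 = dA2 * W.W2.t();

  arma::mat dP1((size_t)B * A.L1p, A.f1, arma::fill::zeros);
  for (int c = 0; c < A.f1; ++c)
    for (int j = 0; j < A.k2; ++j) {
      const int col = c * A.k2 + j;
      for (int b = 0; b < B; ++b) {
        const size_t ro = (size_t)b * A.L2, ri = (size_t)b * A.L1p + j;
        for (int t = 0; t < A.L2; ++t)
          dP1(ri + t, c) += dXc2(ro + t, col);
      }
    }
  if (C.m1.n_elem) dP1 %= C.m1;
  arma::mat dA1((size_t)B * A.L1, A.f1, arma::fill::zeros);
  for (size_t c = 0; c < dP1.n_cols; ++c)
    for (size_t r = 0; r < dP1.n_rows; ++r)
      dA1(C.idx1(r, c), c) += dP1(r, c);
  dA1 %= arma::conv_to<arma::mat>::from(C.A1 > 0);

  G.W1 = C.Xc1.t() * dA1;
  G.b1 = arma::sum(dA1, 0);
}

void rmsprop_step(arma::mat& w, arma::mat& cache, const arma::mat& g,
                  double lr, double rho, double eps) {
  cache = rho * cache + (1.0 - rho) * arma::square(g);
  w -= lr * g / (arma::sqrt(cache) + eps);
}

void rmsprop_step(arma::rowvec& w, arma::rowvec& cache, const arma::rowvec& g,
                  double lr, double rho, double eps) {
  cache = rho * cache + (1.0 - rho) * arma::square(g);
  w -= lr * g / (arma::sqrt(cache) + eps);
}

// Chunked forward over a whole matrix (no dropout); fills probs, and when
// y is given returns mean unweighted CE loss.
double predict_all(const Weights& W, const Arch& A, const arma::mat& X,
                   const arma::ivec* y, arma::mat& probs, int chunk = 512) {
  const int n = X.n_rows;
  probs.set_size(n, A.C);
  double loss = 0.0;
  Cache C;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    arma::mat Xb = X.rows(s, e - 1);
    arma::mat pb;
    if (y) {
      arma::ivec yb = y->subvec(s, e - 1);
      loss += forward(W, A, Xb, &yb, nullptr, false, C, pb) * (e - s);
    } else {
      forward(W, A, Xb, nullptr, nullptr, false, C, pb);
    }
    probs.rows(s, e - 1) = pb;
  }
  return y ? loss / n : NA_REAL;
}

}  // namespace

// [[Rcpp::export]]
List cnn_init_weights(List arch) {
  Arch A = parse_arch(arch);
  RNGScope rng;
  Weights w;
  auto he = [](int rows, int cols, int fan_in) {
    arma::mat m(rows, cols);
    const double sd = std::sqrt(2.0 / fan_in);
    for (size_t i = 0; i < m.n_elem; ++i) m(i) = norm_rand() * sd;
    return m;
  };
  w.W1 = he(A.k1 * A.Cin, A.f1, A.k1 * A.Cin);
  w.W2 = he(A.k2 * A.f1, A.f2, A.k2 * A.f1);
  w.W3 = he(A.flat, A.d1, A.flat);
  w.W4 = he(A.d1, A.C, A.d1);
  w.b1 = arma::rowvec(A.f1, arma::fill::zeros);
  w.b2 = arma::rowvec(A.f2, arma::fill::zeros);
  w.b3 = arma::rowvec(A.d1, arma::fill::zeros);
  w.b4 = arma::rowvec(A.C, arma::fill::zeros);
  return weights_to_list(w);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List weights, NumericMatrix X, List arch) {
  Arch A = parse_arch(arch);
  Weights W = weights_from_list(weights);
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  if ((int)Xa.n_cols != A.Cin * A.M)
    stop("feature dimension (%d) does not match the model (%d x %d bins)",
         (int)Xa.n_cols, A.Cin, A.M);
  arma::mat probs;
  predict_all(W, A, Xa, nullptr, probs);
  return wrap(probs);
}

// Deterministic loss + gradients without dropout; used by the
// finite-difference gradient check.
// [[Rcpp::export]]
List cnn_loss_grad_cpp(List weights, NumericMatrix X, IntegerVector y,
                       List arch) {
  Arch A = parse_arch(arch);
  Weights W = weights_from_list(weights);
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  arma::ivec ya(y.size());
  for (int i = 0; i < y.size(); ++i) ya(i) = y[i];
  Cache C;
  arma::mat probs;
  Arch And = A;
  And.dr1 = And.dr2 = And.dr3 = 0.0;
  double loss = forward(W, And, Xa, &ya, nullptr, false, C, probs);
  Weights G;
  backward(W, And, C, probs, ya, nullptr, G);
  return List::create(_["loss"] = loss, _["grads"] = weights_to_list(G));
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xval,
                   IntegerVector yval, List weights, List arch, List opt) {
  Arch A = parse_arch(arch);
  Weights W = weights_from_list(weights);
  const double lr = as<double>(opt["lr"]);
  const double rho = as<double>(opt["rho"]);
  const double eps = as<double>(opt["eps"]);
  const int batch = as<int>(opt["batch"]);
  const int epochs = as<int>(opt["epochs"]);
  const int patience = as<int>(opt["patience"]);
  const double min_delta = as<double>(opt["min_delta"]);
  const bool verbose = as<bool>(opt["verbose"]);
  arma::vec cw;
  const bool use_cw = opt.containsElementNamed("class_weights") &&
    !Rf_isNull(opt["class_weights"]);
  if (use_cw) cw = as<arma::vec>(opt["class_weights"]);

  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  const int n = Xa.n_rows;
  arma::ivec ya(n);
  for (int i = 0; i < n; ++i) {
    ya(i) = y[i];
    if (ya(i) < 0 || ya(i) >= A.C) stop("class index out of range");
  }
  arma::mat Xv(Xval.begin(), Xval.nrow(), Xval.ncol(), false);
  const int nv = Xv.n_rows;
  arma::ivec yv(std::max(nv, 1));
  for (int i = 0; i < nv; ++i) yv(i) = yval[i];

  RNGScope rng;
  Weights cache, grad;
  cache.W1.zeros(arma::size(W.W1)); cache.W2.zeros(arma::size(W.W2));
  cache.W3.zeros(arma::size(W.W3)); cache.W4.zeros(arma::size(W.W4));
  cache.b1.zeros(W.b1.n_elem); cache.b2.zeros(W.b2.n_elem);
  cache.b3.zeros(W.b3.n_elem); cache.b4.zeros(W.b4.n_elem);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> tr_loss, va_loss, va_acc;
  Weights best = W;
  double best_val = R_PosInf;
  int best_epoch = 0, wait = 0;
  Cache C;

  for (int ep = 1; ep <= epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double esum = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += batch) {
      const int e = std::min(n, s + batch);
      arma::uvec rows(e - s);
      arma::ivec yb(e - s);
      for (int i = s; i < e; ++i) {
        rows(i - s) = idx[i];
        yb(i - s) = ya(idx[i]);
      }
      arma::mat Xb = Xa.rows(rows);
      arma::mat probs;
      esum += forward(W, A, Xb, &yb, use_cw ? &cw : nullptr, true, C, probs);
      ++nb;
      backward(W, A, C, probs, yb, use_cw ? &cw : nullptr, grad);
      rmsprop_step(W.W1, cache.W1, grad.W1, lr, rho, eps);
      rmsprop_step(W.W2, cache.W2, grad.W2, lr, rho, eps);
      rmsprop_step(W.W3, cache.W3, grad.W3, lr, rho, eps);
      rmsprop_step(W.W4, cache.W4, grad.W4, lr, rho, eps);
      rmsprop_step(W.b1, cache.b1, grad.b1, lr, rho, eps);
      rmsprop_step(W.b2, cache.b2, grad.b2, lr, rho, eps);
      rmsprop_step(W.b3, cache.b3, grad.b3, lr, rho, eps);
      rmsprop_step(W.b4, cache.b4, grad.b4, lr, rho, eps);
    }
    tr_loss.push_back(esum / std::max(nb, 1));

    if (nv > 0) {
      arma::mat pv;
      arma::ivec yvv = yv.subvec(0, nv - 1);
      const double vl = predict_all(W, A, Xv, &yvv, pv);
      int correct = 0;
      for (int i = 0; i < nv; ++i)
        if ((int)pv.row(i).index_max() == yvv(i)) ++correct;
      va_loss.push_back(vl);
      va_acc.push_back((double)correct / nv);
      if (verbose)
        Rprintf("epoch %d: train loss %.4f, val loss %.4f, val acc %.3f\n",
                ep, tr_loss.back(), vl, va_acc.back());
      if (vl < best_val - min_delta) {
        best_val = vl;
        best = W;
        best_epoch = ep;
        wait = 0;
      } else if (++wait >= patience && patience > 0) {
        break;
      }
    } else {
      best = W;
      best_epoch = ep;
      if (verbose)
        Rprintf("epoch %d: train loss %.4f\n", ep, tr_loss.back());
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights_to_list(best),
                      _["train_loss"] = tr_loss,
                      _["val_loss"] = va_loss,
                      _["val_acc"] = va_acc,
                      _["best_epoch"] = best_epoch,
                      _["epochs_run"] = (int)tr_loss.size());
}
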