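// Online (per-sample) gradient-descent training loops for the neural-network
// base classifiers. Samples are presented in fixed order 1..n each epoch so
// that training is bitwise reproducible without RNG calls in C++; all weight
// initialisation happens in R from the seeded RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec &z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// Backpropagation network: sigmoid hidden layer, linear output, squared-error
// loss E = sum_j (c_j - t_j)^2 / 2 per sample. Returns trained weights and the
// running training loss (sum of per-sample pre-update losses) per epoch.
// [[Rcpp::export]]
List train_bp_cpp(const arma::mat &X, const arma::mat &Y,
                  arma::mat W1, arma::vec b1, arma::mat W2, arma::vec b2,
                  double lr, int epochs) {
  const arma::uword n = X.n_rows;
  arma::vec loss(epochs, arma::fill::zeros);
  for (int ep = 0; ep < epochs; ++ep) {
    double L = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      arma::vec x = X.row(i).t();
      arma::vec y = Y.row(i).t();
      arma::vec a1 = sigmoid(W1.t() * x + b1);
      arma::vec out = W2.t() * a1 + b2;
      arma::vec err = y - out;                 // E_j = c_j - t_j
      L += 0.5 * arma::dot(err, err);
      arma::vec dOut = -err;                   // dE/dout
      arma::vec dPre = (W2 * dOut) % a1 % (1.0 - a1);
      W2 -= lr * (a1 * dOut.t());
      b2 -= lr * dOut;
      W1 -= lr * (x * dPre.t());
      b1 -= lr * dPre;
    }
    loss[ep] = L;
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["loss"] = loss);
}

// Elman recurrent network. The static feature vector (already zero-padded to
// S * chunk_len columns) is presented as S consecutive chunks; the context
// layer carries alpha-scaled copies of the previous hidden state. Full BPTT
// over the S steps, squared-error loss on the final-step output.
// [[Rcpp::export]]
List train_elman_cpp(const arma::mat &X, const arma::mat &Y,
                     int chunk_len, int n_steps, double alpha,
                     arma::mat Wxh, arma::mat Whh, arma::mat Why,
                     arma::vec bh, arma::vec by,
                     double lr, int epochs) {
  const arma::uword n = X.n_rows;
  const int h = Wxh.n_rows;
  arma::vec loss(epochs, arma::fill::zeros);
  arma::mat hs(h, n_steps);       // hidden states h(f)
  arma::mat ctx(h, n_steps);      // context inputs alpha * q(f-1)
  for (int ep = 0; ep < epochs; ++ep) {
    double L = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      arma::vec y = Y.row(i).t();
      arma::vec q(h, arma::fill::zeros);
      for (int f = 0; f < n_steps; ++f) {
        arma::vec e = X.submat(i, f * chunk_len, i, (f + 1) * chunk_len - 1).t();
        ctx.col(f) = alpha * q;
        q = sigmoid(Wxh * e + Whh * ctx.col(f) + bh);
        hs.col(f) = q;
      }
      arma::vec out = Why * q + by;
      arma::vec err = y - out;
      L += 0.5 * arma::dot(err, err);
      arma::vec dOut = -err;
      arma::mat gWxh(arma::size(Wxh), arma::fill::zeros);
      arma::mat gWhh(arma::size(Whh), arma::fill::zeros);
      arma::vec gbh(h, arma::fill::zeros);
      arma::vec dh = Why.t() * dOut;
      for (int f = n_steps - 1; f >= 0; --f) {
        arma::vec dPre = dh % hs.col(f) % (1.0 - hs.col(f));
        arma::vec e = X.submat(i, f * chunk_len, i, (f + 1) * chunk_len - 1).t();
        gWxh += dPre * e.t();
        gWhh += dPre * ctx.col(f).t();
        gbh += dPre;
        dh = alpha * (Whh.t() * dPre);
      }
      Why -= lr * (dOut * hs.col(n_steps - 1).t());
      by -= lr * dOut;
      Wxh -= lr * gWxh;
      Whh -= lr * gWhh;
      bh -= lr * gbh;
    }
    loss[ep] = L;
  }
  return List::create(_["Wxh"] = Wxh, _["Whh"] = Whh, _["Why"] = Why,
                      _["bh"] = bh, _["by"] = by, _["loss"] = loss);
}

// LVQ1: the winning prototype moves toward the sample if the class labels
// match and away otherwise. y and pclass are 0-based class codes.
// [[Rcpp::export]]
arma::mat train_lvq_cpp(const arma::mat &X, const arma::ivec &y,
                        arma::mat P, const arma::ivec &pclass,
                        double lr, int epochs) {
  const arma::uword n = X.n_rows, np = P.n_rows;
  for (int ep = 0; ep < epochs; ++ep) {
    for (arma::uword i = 0; i < n; ++i) {
      arma::rowvec x = X.row(i);
      arma::uword win = 0;
      double best = arma::datum::inf;
      for (arma::uword p = 0; p < np; ++p) {
        double d = arma::accu(arma::square(x - P.row(p)));
        if (d < best) { best = d; win = p; }
      }
      if (pclass[win] == y[i]) P.row(win) += lr * (x - P.row(win));
      else                     P.row(win) -= lr * (x - P.row(win));
    }
  }
  return P;
}

// Competitive (winner-take-all) network, inner-star rule: only the winning
// prototype is updated, dw = lr * (p - w).
// [[Rcpp::export]]
arma::mat train_competitive_cpp(const arma::mat &X, arma::mat P,
                                double lr, int epochs) {
  const arma::uword n = X.n_rows, np = P.n_rows;
  for (int ep = 0; ep < epochs; ++ep) {
    for (arma::uword i = 0; i < n; ++i) {
      arma::rowvec x = X.row(i);
      arma::uword win = 0;
      double best = arma::datum::inf;
      for (arma::uword p = 0; p < np; ++p) {
        double d = arma::accu(arma::square(x - P.row(p)));
        if (d < best) { best = d; win = p; }
      }
      P.row(win) += lr * (x - P.row(win));
    }
  }
  return P;
}
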