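// Minimal fully connected feed-forward regression network:
// ReLU hidden layers, linear output, mean-squared-error loss, Adam
// optimiser, mini-batch training, and patience-based early stopping on
// validation loss with best-weights restoration.
//
// All randomness (weight init, epoch shuffling) comes from a private
// mt19937 stream seeded by the caller, so fits are bit-reproducible for a
// given seed and independent of R's RNG state.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

double unif01(std::mt19937 &gen) {
  return gen() * (1.0 / 4294967296.0);
}

// Fisher-Yates with our own bounded draw (modulo bias is irrelevant here)
void shuffle_idx(arma::uvec &idx, std::mt19937 &gen) {
  for (arma::uword i = idx.n_elem - 1; i > 0; --i) {
    arma::uword j = gen() % (i + 1);
    std::swap(idx[i], idx[j]);
  }
}

struct Net {
  std::vector<arma::mat> W; // layer l: (out x in)
  std::vector<arma::vec> b;
};

// Glorot-uniform weight initialisation, zero biases
Net init_net(const std::vector<int> &sizes, std::mt19937 &gen) {
  Net net;
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    int fan_in = sizes[l], fan_out = sizes[l + 1];
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    arma::mat W(fan_out, fan_in);
    for (arma::uword k = 0; k < W.n_elem; ++k)
      W[k] = (2.0 * unif01(gen) - 1.0) * lim;
    net.W.push_back(W);
    net.b.push_back(arma::vec(fan_out, arma::fill::zeros));
  }
  return net;
}

// rows of X are samples; returns column vector of predictions
arma::vec net_predict(const Net &net, const arma::mat &X) {
  arma::mat A = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    A = A * net.W[l].t();
    A.each_row() += net.b[l].t();
    if (l + 1 < L) A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  return A.col(0);
}

double mse(const arma::vec &pred, const arma::vec &y) {
  return arma::mean(arma::square(pred - y));
}

} // namespace

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat &Xtr, const arma::vec &ytr,
                   const arma::mat &Xval, const arma::vec &yval,
                   IntegerVector hidden, double lr, int patience,
                   int batch_size, int max_epochs, int seed) {
  std::mt19937 gen(static_cast<uint32_t>(seed));
  std::vector<int> sizes;
  sizes.push_back(Xtr.n_cols);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);

  Net net = init_net(sizes, gen);
  const size_t L = net.W.size();

  // Adam state
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l] = arma::mat(arma::size(net.W[l]), arma::fill::zeros);
    vW[l] = arma::mat(arma::size(net.W[l]), arma::fill::zeros);
    mb[l] = arma::vec(net.b[l].n_elem, arma::fill::zeros);
    vb[l] = arma::vec(net.b[l].n_elem, arma::fill::zeros);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long tstep = 0;

  arma::uvec idx = arma::regspace<arma::uvec>(0, Xtr.n_rows - 1);
  Net best = net;
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  bool finite_ok = true;

  std::vector<arma::mat> A(L + 1), Z(L);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    shuffle_idx(idx, gen);
    for (arma::uword start = 0; start < idx.n_elem;
         start += static_cast<arma::uword>(batch_size)) {
      arma::uword stop = std::min(
          idx.n_elem, start + static_cast<arma::uword>(batch_size));
      arma::uvec bidx = idx.subvec(start, stop - 1);
      const arma::uword nb = bidx.n_elem;

      A[0] = Xtr.rows(bidx);
      for (size_t l = 0; l < L; ++l) {
        Z[l] = A[l] * net.W[l].t();
        Z[l].each_row() += net.b[l].t();
        A[l + 1] = Z[l];
        if (l + 1 < L)
          A[l + 1].transform([](double v) { return v > 0.0 ? v : 0.0; });
      }
      arma::vec err = A[L].col(0) - ytr.elem(bidx);
      if (!err.is_finite()) { finite_ok = false; break; }

      // dZ for the linear output layer
      arma::mat dZ(err.n_elem, 1);
      dZ.col(0) = (2.0 / nb) * err;
      ++tstep;
      const double bc1 = 1.0 - std::pow(b1, (double)tstep);
      const double bc2 = 1.0 - std::pow(b2, (double)tstep);
      for (size_t li = L; li-- > 0;) {
        arma::mat gW = dZ.t() * A[li];
        arma::vec gb = arma::sum(dZ, 0).t();
        if (li > 0) {
          arma::mat dA = dZ * net.W[li];
          dZ = dA % arma::conv_to<arma::mat>::from(Z[li - 1] > 0.0);
        }
        mW[li] = b1 * mW[li] + (1 - b1) * gW;
        vW[li] = b2 * vW[li] + (1 - b2) * arma::square(gW);
        mb[li] = b1 * mb[li] + (1 - b1) * gb;
        vb[li] = b2 * vb[li] + (1 - b2) * arma::square(gb);
        net.W[li] -= lr * (mW[li] / bc1) / (arma::sqrt(vW[li] / bc2) + eps);
        net.b[li] -= lr * (mb[li] / bc1) / (arma::sqrt(vb[li] / bc2) + eps);
      }
    }
    epochs_run = epoch;
    if (!finite_ok) break;

    double val = mse(net_predict(net, Xval), yval);
    if (!std::isfinite(val)) { finite_ok = false; break; }
    if (val < best_val) {
      best_val = val;
      best = net;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  bool failed = !std::isfinite(best_val);
  List Ws(best.W.size()), bs(best.b.size());
  for (size_t l = 0; l < best.W.size(); ++l) {
    Ws[l] = wrap(best.W[l]);
    bs[l] = wrap(best.b[l]);
  }
  return List::create(
      _["weights"] = Ws, _["biases"] = bs, _["val_loss"] = best_val,
      _["epochs_run"] = epochs_run, _["best_epoch"] = best_epoch,
      _["failed"] = failed);
}

// [[Rcpp::export]]
NumericVector mlp_predict_cpp(List weights, List biases, const arma::mat &X) {
  Net net;
  for (int l = 0; l < weights.size(); ++l) {
    net.W.push_back(as<arma::mat>(weights[l]));
    net.b.push_back(as<arma::vec>(biases[l]));
  }
  return wrap(net_predict(net, X));
}
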