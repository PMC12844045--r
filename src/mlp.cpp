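// Fully-connected regression networks (ReLU hidden layers, linear output)
// trained with minibatch AdamW and early stopping on a validation split.
// Written against Armadillo so the large GEMMs go through BLAS.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static std::vector<mat> as_mat_list(const List& x) {
  std::vector<mat> out;
  for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<mat>(x[i]));
  return out;
}

static std::vector<rowvec> as_row_list(const List& x) {
  std::vector<rowvec> out;
  for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<rowvec>(x[i]));
  return out;
}

// forward pass; if acts != nullptr, stores layer inputs for backprop
static vec mlp_forward_impl(const mat& X, const std::vector<mat>& W,
                            const std::vector<rowvec>& b,
                            std::vector<mat>* acts) {
  mat a = X;
  size_t L = W.size();
  if (acts) acts->push_back(a);
  for (size_t l = 0; l + 1 < L; ++l) {
    a = a * W[l];
    a.each_row() += b[l];
    a = arma::clamp(a, 0.0, arma::datum::inf); // ReLU
    if (acts) acts->push_back(a);
  }
  mat out = a * W[L - 1];
  out.each_row() += b[L - 1];
  return out.col(0);
}

// [[Rcpp::export]]
arma::vec mlp_forward_cpp(const arma::mat& X, List W, List b) {
  std::vector<mat> Wv = as_mat_list(W);
  std::vector<rowvec> bv = as_row_list(b);
  return mlp_forward_impl(X, Wv, bv, nullptr);
}

static double val_mse(const mat& X, const vec& y, const std::vector<mat>& W,
                      const std::vector<rowvec>& b) {
  const arma::uword chunk = 8192;
  double sse = 0.0;
  for (arma::uword i = 0; i < X.n_rows; i += chunk) {
    arma::uword j = std::min(i + chunk, X.n_rows) - 1;
    vec p = mlp_forward_impl(X.rows(i, j), W, b, nullptr);
    sse += arma::accu(arma::square(p - y.subvec(i, j)));
  }
  return sse / X.n_rows;
}

// [[Rcpp::export]]
List mlp_fit_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                 const arma::mat& Xval, const arma::vec& yval,
                 List W0, List b0, double lr, double weight_decay,
                 int max_epochs, int patience, int batch_size, int seed) {
  std::vector<mat> W = as_mat_list(W0);
  std::vector<rowvec> b = as_row_list(b0);
  size_t L = W.size();

  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long adam_t = 0;

  std::mt19937 rng(static_cast<unsigned>(seed));
  arma::uword n = Xtr.n_rows;
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<mat> bestW = W;
  std::vector<rowvec> bestb = b;
  double best_val = arma::datum::inf;
  int best_epoch = 0, since_best = 0;
  std::vector<double> tr_log, val_log;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates with explicit draws so shuffling is seed-reproducible
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = rng() % (i + 1);
      std::swap(idx[i], idx[j]);
    }
    double tr_sse = 0.0;
    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      arma::uword end = std::min(start + static_cast<arma::uword>(batch_size),
                                 n) - 1;
      arma::uword B = end - start + 1;
      arma::uvec sel(B);
      for (arma::uword k = 0; k < B; ++k) sel[k] = idx[start + k];
      mat Xb = Xtr.rows(sel);
      vec yb = ytr.elem(sel);

      std::vector<mat> acts;
      vec pred = mlp_forward_impl(Xb, W, b, &acts);
      vec resid = pred - yb;
      tr_sse += arma::accu(arma::square(resid));

      // backprop: dL/dpred for mean squared error over the minibatch
      mat delta = mat(2.0 * resid / static_cast<double>(B));
      std::vector<mat> gW(L);
      std::vector<rowvec> gb(L);
      for (size_t l = L; l-- > 0;) {
        gW[l] = acts[l].t() * delta;
        gb[l] = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<mat>::from(acts[l] > 0.0); // ReLU mask
        }
      }

      ++adam_t;
      double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
      for (size_t l = 0; l < L; ++l) {
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW[l];
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW[l]);
        W[l] -= lr * ((mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps)
                      + weight_decay * W[l]); // decoupled decay
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb[l];
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb[l]);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
    double vloss = val_mse(Xval, yval, W, b);
    tr_log.push_back(tr_sse / n);
    val_log.push_back(vloss);
    if (!std::isfinite(vloss)) stop("Training diverged (non-finite loss).");
    if (vloss < best_val - 1e-12) {
      best_val = vloss;
      bestW = W;
      bestb = b;
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = bestW[l];
    bout[l] = mat(bestb[l]);
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["train_loss"] = tr_log, _["val_loss"] = val_log,
                      _["best_epoch"] = best_epoch, _["best_val"] = best_val);
}
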