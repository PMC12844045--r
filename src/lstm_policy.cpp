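// Recurrent actor-critic: a single LSTM layer shared by the actor and critic,
// each followed by a one-hidden-layer tanh head, plus a global log-std for the
// diagonal Gaussian policy (tanh-squashed). Forward evaluation, the clipped
// PPO loss, and full backpropagation through time are implemented here;
// minibatch order and advantage normalization are supplied from R so all
// randomness stays under R's seeded generator.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LOG_SQRT_2PI = 0.918938533204672741780329736406;

// canonical parameter order
enum ParamIdx { iWx = 0, iWh, ib, iWa1, iba1, iWa2, iba2,
                iWc1, ibc1, iWc2, ibc2, iLogStd, NPARAMS };

static std::vector<mat> unpack(const List& params) {
  std::vector<mat> P(NPARAMS);
  const char* nm[] = {"Wx", "Wh", "b", "Wa1", "ba1", "Wa2", "ba2",
                      "Wc1", "bc1", "Wc2", "bc2", "log_std"};
  for (int k = 0; k < NPARAMS; ++k) P[k] = as<mat>(params[nm[k]]);
  return P;
}

static List pack(const std::vector<mat>& P) {
  return List::create(
    _["Wx"] = P[iWx], _["Wh"] = P[iWh], _["b"] = P[ib],
    _["Wa1"] = P[iWa1], _["ba1"] = P[iba1], _["Wa2"] = P[iWa2],
    _["ba2"] = P[iba2], _["Wc1"] = P[iWc1], _["bc1"] = P[ibc1],
    _["Wc2"] = P[iWc2], _["bc2"] = P[ibc2], _["log_std"] = P[iLogStd]);
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Evaluate a state sequence (T x D) threading hidden state; returns the
// action mean, value estimate and final hidden/cell rows.
// [[Rcpp::export]]
List lstm_policy_seq_cpp(List params, const arma::mat& states,
                         const arma::rowvec& h0, const arma::rowvec& c0) {
  std::vector<mat> P = unpack(params);
  const arma::uword H = P[iWh].n_rows, T = states.n_rows;
  if (P[iWx].n_rows != states.n_cols) stop("State dimension mismatch.");
  rowvec h = h0, c = c0;
  vec mean_out(T), value_out(T);
  for (arma::uword t = 0; t < T; ++t) {
    rowvec gp = states.row(t) * P[iWx] + h * P[iWh] + P[ib];
    rowvec i = 1.0 / (1.0 + arma::exp(-gp.cols(0, H - 1)));
    rowvec f = 1.0 / (1.0 + arma::exp(-gp.cols(H, 2 * H - 1)));
    rowvec g = arma::tanh(gp.cols(2 * H, 3 * H - 1));
    rowvec o = 1.0 / (1.0 + arma::exp(-gp.cols(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    rowvec ah = arma::tanh(h * P[iWa1] + P[iba1]);
    rowvec ch = arma::tanh(h * P[iWc1] + P[ibc1]);
    mean_out(t) = arma::as_scalar(ah * P[iWa2]) + P[iba2](0, 0);
    value_out(t) = arma::as_scalar(ch * P[iWc2]) + P[ibc2](0, 0);
  }
  return List::create(_["mean"] = mean_out, _["value"] = value_out,
                      _["log_std"] = P[iLogStd](0, 0), _["h"] = h, _["c"] = c);
}

struct MbData {
  std::vector<mat> S;       // B x (T x D)
  mat U, OldLp, Adv, Ret;   // B x T
  arma::uword B, T, D;
};

static MbData gather(const List& episodes, const IntegerVector& idx) {
  MbData d;
  d.B = idx.size();
  List e0 = episodes[idx[0] - 1];
  mat s0 = as<mat>(e0["states"]);
  d.T = s0.n_rows;
  d.D = s0.n_cols;
  d.U.set_size(d.B, d.T);
  d.OldLp.set_size(d.B, d.T);
  d.Adv.set_size(d.B, d.T);
  d.Ret.set_size(d.B, d.T);
  for (arma::uword bI = 0; bI < d.B; ++bI) {
    List e = episodes[idx[bI] - 1];
    mat s = as<mat>(e["states"]);
    if (s.n_rows != d.T) stop("Episodes in a minibatch must share length.");
    d.S.push_back(s);
    d.U.row(bI) = as<vec>(e["u"]).t();
    d.OldLp.row(bI) = as<vec>(e["old_logp"]).t();
    d.Adv.row(bI) = as<vec>(e["adv"]).t();
    d.Ret.row(bI) = as<vec>(e["ret"]).t();
  }
  return d;
}

// Forward + clipped loss (+ gradients when grads != nullptr) for one
// minibatch of whole episodes replayed from zero hidden state.
static double minibatch_pass(const std::vector<mat>& P, const MbData& d,
                             double clip_eps, double vf_coef, double ent_coef,
                             std::vector<mat>* grads, vec* metrics) {
  const arma::uword H = P[iWh].n_rows, B = d.B, T = d.T;
  const double N = static_cast<double>(B * T);
  const double log_std = P[iLogStd](0, 0);
  const double sd = std::exp(log_std);

  std::vector<mat> Xs(T), Hs(T), Cs(T), Is(T), Fs(T), Gs(T), Os(T), TCs(T),
      Ahs(T), Chs(T);
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  mat Mean(B, T), Val(B, T);

  for (arma::uword t = 0; t < T; ++t) {
    mat Xt(B, d.D);
    for (arma::uword bI = 0; bI < B; ++bI) Xt.row(bI) = d.S[bI].row(t);
    mat gp = Xt * P[iWx] + h * P[iWh];
    gp.each_row() += rowvec(P[ib]);
    mat I = sigmoid(gp.cols(0, H - 1));
    mat F = sigmoid(gp.cols(H, 2 * H - 1));
    mat G = arma::tanh(gp.cols(2 * H, 3 * H - 1));
    mat O = sigmoid(gp.cols(3 * H, 4 * H - 1));
    mat c_new = F % c + I % G;
    mat tc = arma::tanh(c_new);
    mat h_new = O % tc;
    mat Ah = arma::tanh(h_new * P[iWa1] + arma::repmat(rowvec(P[iba1]), B, 1));
    mat Ch = arma::tanh(h_new * P[iWc1] + arma::repmat(rowvec(P[ibc1]), B, 1));
    Mean.col(t) = Ah * P[iWa2] + P[iba2](0, 0);
    Val.col(t) = Ch * P[iWc2] + P[ibc2](0, 0);
    Xs[t] = Xt; Is[t] = I; Fs[t] = F; Gs[t] = G; Os[t] = O;
    Cs[t] = c; // cell state BEFORE this step (needed for dF)
    TCs[t] = tc; Ahs[t] = Ah; Chs[t] = Ch; Hs[t] = h; // hidden BEFORE step
    c = c_new;
    h = h_new;
  }
  // store post-step hiddens for head backprop
  // reconstruct: h after step t is O%tc
  // loss terms
  mat Z = (d.U - Mean) / sd;
  mat squash_corr = arma::log(1.0 - arma::square(arma::tanh(d.U)) + 1e-6);
  mat NewLp = -0.5 * arma::square(Z) - log_std - LOG_SQRT_2PI - squash_corr;
  mat Ratio = arma::exp(NewLp - d.OldLp);
  mat RatioClip = arma::clamp(Ratio, 1.0 - clip_eps, 1.0 + clip_eps);
  mat Surr1 = Ratio % d.Adv;
  mat Surr2 = RatioClip % d.Adv;
  mat MinSurr = arma::min(Surr1, Surr2);
  double pg_loss = -arma::accu(MinSurr) / N;
  mat Vres = Val - d.Ret;
  double v_loss = vf_coef * arma::accu(arma::square(Vres)) / N;
  double entropy = 0.5 + LOG_SQRT_2PI + log_std; // Gaussian base entropy
  double loss = pg_loss + v_loss - ent_coef * entropy;

  if (metrics) {
    (*metrics)(0) = pg_loss;
    (*metrics)(1) = v_loss / vf_coef;
    (*metrics)(2) = entropy;
    (*metrics)(3) = arma::accu(d.OldLp - NewLp) / N;          // approx KL
    (*metrics)(4) = arma::accu(arma::conv_to<mat>::from(
        arma::abs(Ratio - 1.0) > clip_eps)) / N;              // clip fraction
  }
  if (!grads) return loss;

  std::vector<mat>& Gd = *grads;
  Gd.assign(NPARAMS, mat());
  for (int k = 0; k < NPARAMS; ++k) Gd[k].zeros(P[k].n_rows, P[k].n_cols);

  // d loss / d mean and d loss / d value, per sample
  mat UseUnclipped = arma::conv_to<mat>::from(Surr1 <= Surr2);
  mat dNewLp = -(UseUnclipped % Ratio % d.Adv) / N;
  mat dMean = dNewLp % (Z / sd);
  Gd[iLogStd](0, 0) = arma::accu(dNewLp % (arma::square(Z) - 1.0)) - ent_coef;
  mat dVal = 2.0 * vf_coef * Vres / N;

  mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  for (arma::uword t = T; t-- > 0;) {
    mat h_post = Os[t] % TCs[t];
    // actor head
    mat dm = dMean.col(t);                       // B x 1
    mat dzA = (dm * P[iWa2].t()) % (1.0 - arma::square(Ahs[t]));
    Gd[iWa2] += Ahs[t].t() * dm;
    Gd[iba2](0, 0) += arma::accu(dm);
    Gd[iWa1] += h_post.t() * dzA;
    Gd[iba1] += arma::sum(dzA, 0);
    mat dH = dzA * P[iWa1].t();
    // critic head
    mat dv = dVal.col(t);
    mat dzC = (dv * P[iWc2].t()) % (1.0 - arma::square(Chs[t]));
    Gd[iWc2] += Chs[t].t() * dv;
    Gd[ibc2](0, 0) += arma::accu(dv);
    Gd[iWc1] += h_post.t() * dzC;
    Gd[ibc1] += arma::sum(dzC, 0);
    dH += dzC * P[iWc1].t();

    mat dh = dH + dh_next;
    mat dO = dh % TCs[t];
    mat dc = dc_next + dh % Os[t] % (1.0 - arma::square(TCs[t]));
    mat dI = dc % Gs[t];
    mat dF = dc % Cs[t];
    mat dG = dc % Is[t];
    mat Gp(B, 4 * H);
    Gp.cols(0, H - 1) = dI % Is[t] % (1.0 - Is[t]);
    Gp.cols(H, 2 * H - 1) = dF % Fs[t] % (1.0 - Fs[t]);
    Gp.cols(2 * H, 3 * H - 1) = dG % (1.0 - arma::square(Gs[t]));
    Gp.cols(3 * H, 4 * H - 1) = dO % Os[t] % (1.0 - Os[t]);
    Gd[iWx] += Xs[t].t() * Gp;
    Gd[iWh] += Hs[t].t() * Gp;
    Gd[ib] += arma::sum(Gp, 0);
    dh_next = Gp * P[iWh].t();
    dc_next = dc % Fs[t];
  }
  return loss;
}

// Loss only (used by finite-difference gradient tests).
// [[Rcpp::export]]
double ppo_loss_cpp(List params, List episodes, IntegerVector idx,
                    double clip_eps, double vf_coef, double ent_coef) {
  std::vector<mat> P = unpack(params);
  MbData d = gather(episodes, idx);
  return minibatch_pass(P, d, clip_eps, vf_coef, ent_coef, nullptr, nullptr);
}

// Analytic gradients for one minibatch (used by gradient-check tests).
// [[Rcpp::export]]
List ppo_grad_cpp(List params, List episodes, IntegerVector idx,
                  double clip_eps, double vf_coef, double ent_coef) {
  std::vector<mat> P = unpack(params);
  MbData d = gather(episodes, idx);
  std::vector<mat> grads;
  double loss = minibatch_pass(P, d, clip_eps, vf_coef, ent_coef, &grads,
                               nullptr);
  return List::create(_["loss"] = loss, _["grads"] = pack(grads));
}

// One PPO update: several epochs of minibatch Adam steps over whole episodes.
// `order` is a list of 1-based episode-index vectors, one entry per minibatch
// (epoch structure already flattened by the caller).
// [[Rcpp::export]]
List ppo_update_cpp(List params, List adam, List episodes, List order,
                    double lr, double clip_eps, double vf_coef,
                    double ent_coef, double max_grad_norm, double target_kl) {
  std::vector<mat> P = unpack(params);
  std::vector<mat> M = unpack(as<List>(adam["m"]));
  std::vector<mat> V = unpack(as<List>(adam["v"]));
  long adam_t = as<long>(adam["t"]);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  int n_mb = order.size();
  mat metrics(n_mb, 5, arma::fill::value(arma::datum::nan));
  int used_mb = 0;
  for (int k = 0; k < n_mb; ++k) {
    IntegerVector idx = order[k];
    MbData d = gather(episodes, idx);
    std::vector<mat> grads;
    vec mrow(5);
    double loss = minibatch_pass(P, d, clip_eps, vf_coef, ent_coef, &grads,
                                 &mrow);
    if (!std::isfinite(loss)) stop("PPO update diverged (non-finite loss).");
    metrics.row(k) = mrow.t();
    ++used_mb;
    // stop optimizing this buffer once the policy has moved far enough
    if (target_kl > 0 && mrow(3) > target_kl) break;

    double sq = 0.0;
    for (int j = 0; j < NPARAMS; ++j) sq += arma::accu(arma::square(grads[j]));
    double gnorm = std::sqrt(sq);
    if (gnorm > max_grad_norm && gnorm > 0) {
      double s = max_grad_norm / gnorm;
      for (int j = 0; j < NPARAMS; ++j) grads[j] *= s;
    }
    ++adam_t;
    double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
    double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
    for (int j = 0; j < NPARAMS; ++j) {
      M[j] = beta1 * M[j] + (1 - beta1) * grads[j];
      V[j] = beta2 * V[j] + (1 - beta2) * arma::square(grads[j]);
      P[j] -= lr * (M[j] / bc1) / (arma::sqrt(V[j] / bc2) + eps);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["params"] = pack(P),
    _["adam"] = List::create(_["m"] = pack(M), _["v"] = pack(V),
                             _["t"] = (double)adam_t),
    _["metrics"] = metrics.rows(0, used_mb - 1));
}
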