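// Core numerics: overdamped Langevin integration on 2-D model potentials,
// and the embedding + LSTM + softmax sequence model (forward pass,
// backpropagation through time, Adam/SGD updates, autoregressive sampling).
// All randomness is drawn from R's RNG (unif_rand / norm_rand) so that
// set.seed() on the R side makes every entry point reproducible.
//
// Gate layout inside the stacked 4L-row matrices: rows [0,L) input gate i,
// [L,2L) forget gate f, [2L,3L) candidate g (tanh), [3L,4L) output gate o.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// ---------------------------------------------------------------------------
// Langevin dynamics
// ---------------------------------------------------------------------------

// gradient of U(x,y) = W (x^d + y^d) + sum_i s_i G(x; cx_i) G(y; cy_i)
static inline void potential_grad(double x, double y, double W, int degree,
                                  const mat& centers, const vec& signs,
                                  const vec& sigmas, double& gx, double& gy) {
  gx = W * degree * std::pow(x, degree - 1);
  gy = W * degree * std::pow(y, degree - 1);
  for (uword i = 0; i < signs.n_elem; ++i) {
    const double s2 = sigmas[i] * sigmas[i];
    const double dx = x - centers(i, 0), dy = y - centers(i, 1);
    const double g = signs[i] * std::exp(-(dx * dx + dy * dy) / (2.0 * s2));
    gx += g * (-dx / s2);
    gy += g * (-dy / s2);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_langevin(double W, int degree, const arma::mat& centers,
                        const arma::vec& signs, const arma::vec& sigmas,
                        double beta, double dt, double n_steps_d, int stride,
                        double x0, double y0) {
  const long long n_steps = (long long)n_steps_d;
  const long long n_out = n_steps / stride;
  const double noise = std::isfinite(beta) ? std::sqrt(2.0 * dt / beta) : 0.0;
  vec xs(n_out), ys(n_out);
  double x = x0, y = y0, gx, gy;
  Rcpp::RNGScope scope;
  long long k = 0;
  for (long long step = 1; step <= n_steps; ++step) {
    potential_grad(x, y, W, degree, centers, signs, sigmas, gx, gy);
    x += -gx * dt + noise * norm_rand();
    y += -gy * dt + noise * norm_rand();
    if (!std::isfinite(x) || !std::isfinite(y))
      Rcpp::stop("Langevin integration diverged at step %lld", step);
    if (step % stride == 0) {
      xs[k] = x;
      ys[k] = y;
      ++k;
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = xs, Rcpp::Named("y") = ys);
}

// ---------------------------------------------------------------------------
// LSTM parameter bundle
// ---------------------------------------------------------------------------

struct Params {
  mat emb;  // M x N
  mat Wx;   // 4L x M
  mat Uh;   // 4L x L
  vec b;    // 4L
  mat D;    // N x L
  vec bd;   // N
};

static Params params_from_list(const Rcpp::List& lst) {
  Params p;
  p.emb = Rcpp::as<mat>(lst["embedding"]);
  p.Wx = Rcpp::as<mat>(lst["W"]);
  p.Uh = Rcpp::as<mat>(lst["U"]);
  p.b = Rcpp::as<vec>(lst["b"]);
  p.D = Rcpp::as<mat>(lst["D"]);
  p.bd = Rcpp::as<vec>(lst["b_d"]);
  return p;
}

static Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("embedding") = p.emb, Rcpp::Named("W") = p.Wx,
      Rcpp::Named("U") = p.Uh, Rcpp::Named("b") = p.b, Rcpp::Named("D") = p.D,
      Rcpp::Named("b_d") = p.bd);
}

static Params params_zeros_like(const Params& p) {
  Params z;
  z.emb = zeros<mat>(p.emb.n_rows, p.emb.n_cols);
  z.Wx = zeros<mat>(p.Wx.n_rows, p.Wx.n_cols);
  z.Uh = zeros<mat>(p.Uh.n_rows, p.Uh.n_cols);
  z.b = zeros<vec>(p.b.n_elem);
  z.D = zeros<mat>(p.D.n_rows, p.D.n_cols);
  z.bd = zeros<vec>(p.bd.n_elem);
  return z;
}

static inline mat sigmoid(const mat& a) { return 1.0 / (1.0 + exp(-a)); }

// ---------------------------------------------------------------------------
// Teacher-forced forward pass (+ optional BPTT) over a batch of windows.
// inputs / targets: T x B label matrices (0-based). Returns summed
// cross-entropy in nats over all T*B predictions; gradients of the summed
// loss are accumulated into `g` when do_grad is true.
// ---------------------------------------------------------------------------

static double fwd_bwd(const Params& p, const umat& inputs, const umat& targets,
                      Params* g) {
  const uword T = inputs.n_rows, B = inputs.n_cols;
  const uword L = p.Uh.n_cols, M = p.emb.n_rows, N = p.emb.n_cols;
  const bool do_grad = g != nullptr;

  cube Xs, Is, Fs, Gs, Os, Cs, TCs, Hs, Ps;
  if (do_grad) {
    Xs.set_size(M, B, T);
    Is.set_size(L, B, T);
    Fs.set_size(L, B, T);
    Gs.set_size(L, B, T);
    Os.set_size(L, B, T);
    Cs.set_size(L, B, T);
    TCs.set_size(L, B, T);
    Hs.set_size(L, B, T);
    Ps.set_size(N, B, T);
  }

  mat H(L, B, fill::zeros), C(L, B, fill::zeros);
  double loss = 0.0;
  for (uword t = 0; t < T; ++t) {
    const uvec idx = inputs.row(t).t();
    const mat X = p.emb.cols(idx);
    mat A = p.Wx * X + p.Uh * H;
    A.each_col() += p.b;
    const mat I = sigmoid(A.rows(0, L - 1));
    const mat F = sigmoid(A.rows(L, 2 * L - 1));
    const mat G = tanh(A.rows(2 * L, 3 * L - 1));
    const mat O = sigmoid(A.rows(3 * L, 4 * L - 1));
    C = F % C + I % G;
    const mat TC = tanh(C);
    H = O % TC;

    mat logits = p.D * H;
    logits.each_col() += p.bd;
    const rowvec mx = max(logits, 0);
    const mat E = exp(logits.each_row() - mx);
    const rowvec Z = sum(E, 0);
    for (uword bcol = 0; bcol < B; ++bcol)
      loss += std::log(Z[bcol]) + mx[bcol] - logits(targets(t, bcol), bcol);

    if (do_grad) {
      Xs.slice(t) = X;
      Is.slice(t) = I;
      Fs.slice(t) = F;
      Gs.slice(t) = G;
      Os.slice(t) = O;
      Cs.slice(t) = C;
      TCs.slice(t) = TC;
      Hs.slice(t) = H;
      Ps.slice(t) = E.each_row() / Z;
    }
  }
  if (!do_grad) return loss;

  mat dH(L, B, fill::zeros), dC(L, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    mat dLogit = Ps.slice(tt);
    for (uword bcol = 0; bcol < B; ++bcol) dLogit(targets(tt, bcol), bcol) -= 1.0;
    g->D += dLogit * Hs.slice(tt).t();
    g->bd += sum(dLogit, 1);
    dH += p.D.t() * dLogit;

    const mat& I = Is.slice(tt);
    const mat& F = Fs.slice(tt);
    const mat& G = Gs.slice(tt);
    const mat& O = Os.slice(tt);
    const mat& TC = TCs.slice(tt);
    const mat Cprev = (tt == 0) ? mat(L, B, fill::zeros) : Cs.slice(tt - 1);
    const mat Hprev = (tt == 0) ? mat(L, B, fill::zeros) : Hs.slice(tt - 1);

    dC += dH % O % (1.0 - TC % TC);
    mat dA(4 * L, B);
    dA.rows(0, L - 1) = (dC % G) % I % (1.0 - I);
    dA.rows(L, 2 * L - 1) = (dC % Cprev) % F % (1.0 - F);
    dA.rows(2 * L, 3 * L - 1) = (dC % I) % (1.0 - G % G);
    dA.rows(3 * L, 4 * L - 1) = (dH % TC) % O % (1.0 - O);

    g->Wx += dA * Xs.slice(tt).t();
    g->Uh += dA * Hprev.t();
    g->b += sum(dA, 1);
    const mat dX = p.Wx.t() * dA;
    for (uword bcol = 0; bcol < B; ++bcol)
      g->emb.col(inputs(tt, bcol)) += dX.col(bcol);
    dH = p.Uh.t() * dA;
    dC = dC % F;
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Window bookkeeping
// ---------------------------------------------------------------------------

// non-overlapping windows of seq_len inputs (+1 target lookahead) whose
// indices stay inside [from, to)
static std::vector<uword> window_starts(uword from, uword to, uword seq_len) {
  std::vector<uword> st;
  if (to < from + seq_len + 1) return st;
  for (uword s = from; s + seq_len + 1 <= to; s += seq_len) st.push_back(s);
  return st;
}

static void fill_batch(const uvec& labels, const std::vector<uword>& starts,
                       uword first, uword nb, uword seq_len, umat& inputs,
                       umat& targets) {
  inputs.set_size(seq_len, nb);
  targets.set_size(seq_len, nb);
  for (uword j = 0; j < nb; ++j) {
    const uword s = starts[first + j];
    for (uword t = 0; t < seq_len; ++t) {
      inputs(t, j) = labels[s + t];
      targets(t, j) = labels[s + t + 1];
    }
  }
}

static double eval_windows(const Params& p, const uvec& labels,
                           const std::vector<uword>& starts, uword seq_len,
                           uword batch_size) {
  if (starts.empty()) return NA_REAL;
  double tot = 0.0;
  uword nsym = 0;
  umat inputs, targets;
  for (uword first = 0; first < starts.size(); first += batch_size) {
    const uword nb = std::min<uword>(batch_size, starts.size() - first);
    fill_batch(labels, starts, first, nb, seq_len, inputs, targets);
    tot += fwd_bwd(p, inputs, targets, nullptr);
    nsym += nb * seq_len;
  }
  return tot / nsym;
}

// Fisher-Yates shuffle driven by R's RNG
static void shuffle_starts(std::vector<uword>& v) {
  for (size_t i = v.size(); i > 1; --i) {
    size_t j = (size_t)(unif_rand() * i);
    if (j >= i) j = i - 1;
    std::swap(v[i - 1], v[j]);
  }
}

// ---------------------------------------------------------------------------
// Training loop: Adam (default) or plain SGD, gradient clipping by global
// norm, contiguous tail validation split.
// ---------------------------------------------------------------------------

template <typename F>
static void for_each_tensor(Params& p, F f) {
  f(p.emb);
  f(p.Wx);
  f(p.Uh);
  f(p.b);
  f(p.D);
  f(p.bd);
}

// [[Rcpp::export]]
Rcpp::List cpp_train(const arma::uvec& labels, const Rcpp::List& init_params,
                     int seq_len, int batch_size, int epochs, double lr,
                     std::string optimizer, double val_frac, double clip_norm) {
  Params p = params_from_list(init_params);
  const uword S = labels.n_elem;
  const uword n_train = val_frac > 0 ? (uword)std::floor(S * (1.0 - val_frac)) : S;
  std::vector<uword> train_starts = window_starts(0, n_train, seq_len);
  const std::vector<uword> val_starts = window_starts(n_train, S, seq_len);
  if (train_starts.empty())
    Rcpp::stop("label series too short: no training window of seq_len %d fits",
               seq_len);

  const bool adam = optimizer == "adam";
  Params m = params_zeros_like(p), v = params_zeros_like(p),
         grad = params_zeros_like(p);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long long step = 0;

  std::vector<double> train_hist, val_hist;
  Rcpp::RNGScope scope;
  umat inputs, targets;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    shuffle_starts(train_starts);
    double tot = 0.0;
    uword nsym = 0;
    for (uword first = 0; first < train_starts.size(); first += batch_size) {
      const uword nb =
          std::min<uword>(batch_size, train_starts.size() - first);
      fill_batch(labels, train_starts, first, nb, seq_len, inputs, targets);
      for_each_tensor(grad, [](arma::Mat<double>& x) { x.zeros(); });
      const double l = fwd_bwd(p, inputs, targets, &grad);
      if (!std::isfinite(l))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d",
                   epoch + 1);
      tot += l;
      nsym += nb * seq_len;
      const double scale = 1.0 / (nb * seq_len);  // per-symbol mean gradient
      for_each_tensor(grad, [&](arma::Mat<double>& x) { x *= scale; });
      double sq = 0.0;
      for_each_tensor(grad,
                      [&](arma::Mat<double>& x) { sq += accu(x % x); });
      const double gnorm = std::sqrt(sq);
      if (clip_norm > 0 && gnorm > clip_norm) {
        const double cs = clip_norm / gnorm;
        for_each_tensor(grad, [&](arma::Mat<double>& x) { x *= cs; });
      }
      ++step;
      if (adam) {
        const double bc1 = 1.0 - std::pow(beta1, (double)step);
        const double bc2 = 1.0 - std::pow(beta2, (double)step);
        auto upd = [&](mat& w, mat& mm, mat& vv, mat& gg) {
          mm = beta1 * mm + (1 - beta1) * gg;
          vv = beta2 * vv + (1 - beta2) * (gg % gg);
          w -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
        };
        auto updv = [&](vec& w, vec& mm, vec& vv, vec& gg) {
          mm = beta1 * mm + (1 - beta1) * gg;
          vv = beta2 * vv + (1 - beta2) * (gg % gg);
          w -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
        };
        upd(p.emb, m.emb, v.emb, grad.emb);
        upd(p.Wx, m.Wx, v.Wx, grad.Wx);
        upd(p.Uh, m.Uh, v.Uh, grad.Uh);
        updv(p.b, m.b, v.b, grad.b);
        upd(p.D, m.D, v.D, grad.D);
        updv(p.bd, m.bd, v.bd, grad.bd);
      } else {
        p.emb -= lr * grad.emb;
        p.Wx -= lr * grad.Wx;
        p.Uh -= lr * grad.Uh;
        p.b -= lr * grad.b;
        p.D -= lr * grad.D;
        p.bd -= lr * grad.bd;
      }
      Rcpp::checkUserInterrupt();
    }
    train_hist.push_back(tot / nsym);
    val_hist.push_back(eval_windows(p, labels, val_starts, seq_len, batch_size));
  }

  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(p),
                            Rcpp::Named("train_loss") = train_hist,
                            Rcpp::Named("val_loss") = val_hist,
                            Rcpp::Named("n_train_windows") =
                                (double)train_starts.size(),
                            Rcpp::Named("n_val_windows") =
                                (double)val_starts.size());
}

// ---------------------------------------------------------------------------
// Whole-sequence teacher-forced loss (single sequence)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_sequence_loss(const Rcpp::List& params_list,
                             const arma::uvec& labels) {
  const Params p = params_from_list(params_list);
  const uword T = labels.n_elem - 1;
  umat inputs(T, 1), targets(T, 1);
  for (uword t = 0; t < T; ++t) {
    inputs(t, 0) = labels[t];
    targets(t, 0) = labels[t + 1];
  }
  const double tot = fwd_bwd(p, inputs, targets, nullptr);
  return Rcpp::List::create(Rcpp::Named("total") = tot,
                            Rcpp::Named("per_symbol") = tot / T);
}

// ---------------------------------------------------------------------------
// Single-step machinery for conditioning and sampling
// ---------------------------------------------------------------------------

static void step1(const Params& p, uword label, vec& h, vec& c, vec& probs) {
  const uword L = p.Uh.n_cols;
  vec a = p.Wx * p.emb.col(label) + p.Uh * h + p.b;
  const vec I = 1.0 / (1.0 + exp(-a.subvec(0, L - 1)));
  const vec F = 1.0 / (1.0 + exp(-a.subvec(L, 2 * L - 1)));
  const vec G = tanh(a.subvec(2 * L, 3 * L - 1));
  const vec O = 1.0 / (1.0 + exp(-a.subvec(3 * L, 4 * L - 1)));
  c = F % c + I % G;
  h = O % tanh(c);
  vec logits = p.D * h + p.bd;
  logits -= logits.max();
  probs = exp(logits);
  probs /= accu(probs);
}

// [[Rcpp::export]]
arma::vec cpp_conditional_probs(const Rcpp::List& params_list,
                                const arma::uvec& context) {
  const Params p = params_from_list(params_list);
  const uword L = p.Uh.n_cols;
  vec h(L, fill::zeros), c(L, fill::zeros), probs;
  for (uword t = 0; t < context.n_elem; ++t) step1(p, context[t], h, c, probs);
  return probs;
}

// [[Rcpp::export]]
arma::uvec cpp_sample(const Rcpp::List& params_list, const arma::uvec& context,
                      double n_out_d, int burn_in) {
  const Params p = params_from_list(params_list);
  const uword L = p.Uh.n_cols;
  const long long n_out = (long long)n_out_d;
  vec h(L, fill::zeros), c(L, fill::zeros), probs;
  Rcpp::RNGScope scope;
  for (uword t = 0; t < context.n_elem; ++t) step1(p, context[t], h, c, probs);
  uvec out(n_out);
  long long k = 0;
  for (long long i = 0; i < n_out + burn_in; ++i) {
    const double u = unif_rand();
    double acc = 0.0;
    uword next = probs.n_elem - 1;
    for (uword j = 0; j < probs.n_elem; ++j) {
      acc += probs[j];
      if (u < acc) {
        next = j;
        break;
      }
    }
    if (i >= burn_in) out[k++] = next;
    step1(p, next, h, c, probs);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
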