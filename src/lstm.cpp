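#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

// Two-layer LSTM regressor over 13-dimensional, 200-step MFCC sequences:
// each recurrent layer has U units, the final hidden state feeds a
// rectified fully connected layer of F units and a linear scalar output.
// Squared-error loss, Adam updates, learning rate halved every
// `lr_halving_period` epochs. All randomness (initialization, shuffling)
// comes from a private mt19937 stream so runs are reproducible.

struct Params {
  mat W1x, W1h, W2x, W2h, Wf, Wo;
  vec b1, b2, bf, bo;
};

static Params unpack(const List& p) {
  Params P;
  P.W1x = as<mat>(p["W1x"]); P.W1h = as<mat>(p["W1h"]); P.b1 = as<vec>(p["b1"]);
  P.W2x = as<mat>(p["W2x"]); P.W2h = as<mat>(p["W2h"]); P.b2 = as<vec>(p["b2"]);
  P.Wf  = as<mat>(p["Wf"]);  P.bf  = as<vec>(p["bf"]);
  P.Wo  = as<mat>(p["Wo"]);  P.bo  = as<vec>(p["bo"]);
  return P;
}

static List pack(const Params& P) {
  return List::create(
    _["W1x"] = P.W1x, _["W1h"] = P.W1h, _["b1"] = P.b1,
    _["W2x"] = P.W2x, _["W2h"] = P.W2h, _["b2"] = P.b2,
    _["Wf"] = P.Wf, _["bf"] = P.bf, _["Wo"] = P.Wo, _["bo"] = P.bo);
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// [[Rcpp::export]]
List lstm_init_cpp(int D, int U, int F, int seed) {
  std::mt19937 rng(seed);
  auto init = [&](int r, int c) {
    double s = 1.0 / std::sqrt((double)c);
    std::uniform_real_distribution<double> u(-s, s);
    mat M(r, c);
    for (arma::uword j = 0; j < M.n_cols; ++j)
      for (arma::uword i = 0; i < M.n_rows; ++i) M(i, j) = u(rng);
    return M;
  };
  Params P;
  P.W1x = init(4 * U, D); P.W1h = init(4 * U, U);
  P.b1 = vec(4 * U, arma::fill::zeros); P.b1.subvec(U, 2 * U - 1).fill(1.0);
  P.W2x = init(4 * U, U); P.W2h = init(4 * U, U);
  P.b2 = vec(4 * U, arma::fill::zeros); P.b2.subvec(U, 2 * U - 1).fill(1.0);
  P.Wf = init(F, U); P.bf = vec(F, arma::fill::zeros);
  P.Wo = init(1, F); P.bo = vec(1, arma::fill::zeros);
  return pack(P);
}

struct Cache {
  cube I, Fg, G, O, C, H;   // gate activations, cell and hidden states (B x U x T)
  Cache(int B, int U, int T)
    : I(B, U, T), Fg(B, U, T), G(B, U, T), O(B, U, T), C(B, U, T), H(B, U, T) {}
};

// forward one LSTM layer over the whole batch; Xseq holds the layer input as
// a (B x Din x T) cube; gates/cells are written into cache when training
static void layer_forward(const cube& Xseq, const mat& Wx, const mat& Wh,
                          const vec& b, int U, Cache* cache, mat& h_out) {
  const int B = Xseq.n_rows, T = Xseq.n_slices;
  mat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat a = Xseq.slice(t) * Wx.t() + h * Wh.t();
    a.each_row() += b.t();
    mat i = sigm(a.cols(0, U - 1));
    mat f = sigm(a.cols(U, 2 * U - 1));
    mat g = arma::tanh(a.cols(2 * U, 3 * U - 1));
    mat o = sigm(a.cols(3 * U, 4 * U - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    if (cache) {
      cache->I.slice(t) = i; cache->Fg.slice(t) = f; cache->G.slice(t) = g;
      cache->O.slice(t) = o; cache->C.slice(t) = c; cache->H.slice(t) = h;
    }
  }
  h_out = h;
}

// gather samples idx (0-based) of X (D x T x N) into a (B x D x T) cube
static cube gather(const cube& X, const std::vector<int>& idx) {
  const int D = X.n_rows, T = X.n_cols, B = idx.size();
  cube out(B, D, T);
  for (int b = 0; b < B; ++b) {
    const mat& sl = X.slice(idx[b]);           // D x T
    for (int t = 0; t < T; ++t)
      out.slice(t).row(b) = sl.col(t).t();
  }
  return out;
}

static vec head_forward(const mat& h2, const Params& P, mat* fc_out, mat* fcpre_out) {
  mat fcpre = h2 * P.Wf.t();
  fcpre.each_row() += P.bf.t();
  mat fc = arma::max(fcpre, arma::zeros<mat>(fcpre.n_rows, fcpre.n_cols));
  vec yhat = fc * P.Wo.t() + P.bo(0);
  if (fc_out) *fc_out = fc;
  if (fcpre_out) *fcpre_out = fcpre;
  return yhat;
}

// backward through one LSTM layer; returns gradient w.r.t. the layer input
// sequence; dH_in holds per-step incoming dL/dh (may be zero except last step)
static cube layer_backward(const cube& Xseq, const Cache& cc, const mat& Wx,
                           const mat& Wh, int U, const cube& dH_in,
                           mat& dWx, mat& dWh, vec& db) {
  const int B = Xseq.n_rows, T = Xseq.n_slices;
  dWx.zeros(); dWh.zeros(); db.zeros();
  cube dX(B, Xseq.n_cols, T, arma::fill::zeros);
  mat dh(B, U, arma::fill::zeros), dc(B, U, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH_in.slice(t);
    const mat& i = cc.I.slice(t); const mat& f = cc.Fg.slice(t);
    const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
    mat tanhc = arma::tanh(cc.C.slice(t));
    mat do_ = dh % tanhc;
    dc += dh % o % (1.0 - tanhc % tanhc);
    mat cprev = (t > 0) ? cc.C.slice(t - 1)
                        : mat(B, U, arma::fill::zeros);
    mat di = dc % g, dg = dc % i, df = dc % cprev;
    mat da(B, 4 * U);
    da.cols(0, U - 1)         = di % i % (1.0 - i);
    da.cols(U, 2 * U - 1)     = df % f % (1.0 - f);
    da.cols(2 * U, 3 * U - 1) = dg % (1.0 - g % g);
    da.cols(3 * U, 4 * U - 1) = do_ % o % (1.0 - o);
    mat hprev = (t > 0) ? cc.H.slice(t - 1)
                        : mat(B, U, arma::fill::zeros);
    dWx += da.t() * Xseq.slice(t);
    dWh += da.t() * hprev;
    db  += arma::sum(da, 0).t();
    dX.slice(t) = da * Wx;
    dh = da * Wh;
    dc = dc % f;
  }
  return dX;
}

struct Grads {
  mat W1x, W1h, W2x, W2h, Wf, Wo;
  vec b1, b2, bf, bo;
};

static double loss_and_grads(const cube& Xb, const vec& yb, const Params& P,
                             int U, Grads& G) {
  const int B = Xb.n_rows, T = Xb.n_slices;
  Cache c1(B, U, T), c2(B, U, T);
  mat h1T, h2T;
  layer_forward(Xb, P.W1x, P.W1h, P.b1, U, &c1, h1T);
  cube H1 = c1.H;   // layer-2 input sequence
  layer_forward(H1, P.W2x, P.W2h, P.b2, U, &c2, h2T);
  mat fc, fcpre;
  vec yhat = head_forward(h2T, P, &fc, &fcpre);
  vec err = yhat - yb;
  double loss = arma::dot(err, err) / B;

  vec dyhat = 2.0 * err / B;
  G.Wo = dyhat.t() * fc;
  G.bo = vec(1); G.bo(0) = arma::sum(dyhat);
  mat dfc = dyhat * P.Wo;
  dfc.elem(arma::find(fcpre <= 0)).zeros();
  G.Wf = dfc.t() * h2T;
  G.bf = arma::sum(dfc, 0).t();
  mat dh2T = dfc * P.Wf;

  cube dH2(B, U, T, arma::fill::zeros);
  dH2.slice(T - 1) = dh2T;
  G.W2x.set_size(arma::size(P.W2x)); G.W2h.set_size(arma::size(P.W2h));
  G.b2.set_size(P.b2.n_elem);
  cube dH1 = layer_backward(H1, c2, P.W2x, P.W2h, U, dH2, G.W2x, G.W2h, G.b2);
  G.W1x.set_size(arma::size(P.W1x)); G.W1h.set_size(arma::size(P.W1h));
  G.b1.set_size(P.b1.n_elem);
  layer_backward(Xb, c1, P.W1x, P.W1h, U, dH1, G.W1x, G.W1h, G.b1);
  return loss;
}

struct Adam {
  mat m, v;
  Adam() {}
  void init(const mat& like) { m.zeros(arma::size(like)); v.zeros(arma::size(like)); }
  void step(mat& w, const mat& g, double lr, long t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    mat mh = m / (1.0 - std::pow(0.9, (double)t));
    mat vh = v / (1.0 - std::pow(0.999, (double)t));
    w -= lr * mh / (arma::sqrt(vh) + 1e-8);
  }
};

// [[Rcpp::export]]
List lstm_train_cpp(const arma::cube& X, const arma::vec& y, List params,
                    int U, int epochs, int batch_size, double initial_lr,
                    int lr_halving_period, int seed) {
  const int N = X.n_slices;
  if ((int)y.n_elem != N) stop("label count does not match sample count");
  Params P = unpack(params);
  Grads G;
  Adam aW1x, aW1h, aW2x, aW2h, aWf, aWo, ab1, ab2, abf, abo;
  aW1x.init(P.W1x); aW1h.init(P.W1h); aW2x.init(P.W2x); aW2h.init(P.W2h);
  aWf.init(P.Wf); aWo.init(P.Wo);
  ab1.init(mat(P.b1)); ab2.init(mat(P.b2)); abf.init(mat(P.bf)); abo.init(mat(P.bo));

  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  NumericVector history(epochs);
  long step = 0;

  for (int e = 0; e < epochs; ++e) {
    double lr = initial_lr * std::pow(0.5, e / lr_halving_period);
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0; int nb = 0;
    for (int s0 = 0; s0 < N; s0 += batch_size) {
      int s1 = std::min(N, s0 + batch_size);
      std::vector<int> idx(order.begin() + s0, order.begin() + s1);
      cube Xb = gather(X, idx);
      vec yb(idx.size());
      for (size_t b = 0; b < idx.size(); ++b) yb(b) = y(idx[b]);
      double loss = loss_and_grads(Xb, yb, P, U, G);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d (lr %.2g)", e, lr);
      ++step;
      aW1x.step(P.W1x, G.W1x, lr, step); aW1h.step(P.W1h, G.W1h, lr, step);
      aW2x.step(P.W2x, G.W2x, lr, step); aW2h.step(P.W2h, G.W2h, lr, step);
      aWf.step(P.Wf, G.Wf, lr, step);    aWo.step(P.Wo, G.Wo, lr, step);
      { mat b = mat(P.b1); ab1.step(b, mat(G.b1), lr, step); P.b1 = b.col(0); }
      { mat b = mat(P.b2); ab2.step(b, mat(G.b2), lr, step); P.b2 = b.col(0); }
      { mat b = mat(P.bf); abf.step(b, mat(G.bf), lr, step); P.bf = b.col(0); }
      { mat b = mat(P.bo); abo.step(b, mat(G.bo), lr, step); P.bo = b.col(0); }
      tot += loss; ++nb;
      if (nb % 16 == 0) Rcpp::checkUserInterrupt();
    }
    history[e] = tot / std::max(nb, 1);
  }
  return List::create(_["params"] = pack(P), _["loss_history"] = history);
}

// [[Rcpp::export]]
NumericVector lstm_predict_cpp(const arma::cube& X, List params, int U,
                               int batch_size = 256) {
  const int N = X.n_slices;
  Params P = unpack(params);
  NumericVector out(N);
  for (int s0 = 0; s0 < N; s0 += batch_size) {
    int s1 = std::min(N, s0 + batch_size);
    std::vector<int> idx;
    for (int i = s0; i < s1; ++i) idx.push_back(i);
    cube Xb = gather(X, idx);
    mat h1T, h2T;
    Cache c1(Xb.n_rows, U, Xb.n_slices);
    layer_forward(Xb, P.W1x, P.W1h, P.b1, U, &c1, h1T);
    layer_forward(c1.H, P.W2x, P.W2h, P.b2, U, nullptr, h2T);
    vec yhat = head_forward(h2T, P, nullptr, nullptr);
    for (int i = s0; i < s1; ++i) out[i] = yhat(i - s0);
  }
  return out;
}

// loss and flattened analytic gradient for gradient-checking tests
// [[Rcpp::export]]
List lstm_loss_grad_cpp(const arma::cube& X, const arma::vec& y, List params,
                        int U) {
  std::vector<int> idx;
  for (int i = 0; i < (int)X.n_slices; ++i) idx.push_back(i);
  cube Xb = gather(X, idx);
  Params P = unpack(params);
  Grads G;
  double loss = loss_and_grads(Xb, y, P, U, G);
  return List::create(_["loss"] = loss,
    _["grads"] = List::create(
      _["W1x"] = G.W1x, _["W1h"] = G.W1h, _["b1"] = G.b1,
      _["W2x"] = G.W2x, _["W2h"] = G.W2h, _["b2"] = G.b2,
      _["Wf"] = G.Wf, _["bf"] = G.bf, _["Wo"] = G.Wo, _["bo"] = G.bo));
}
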