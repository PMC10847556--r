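#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Duration-dependent Viterbi decoding over the four cyclic cardiac states
// (S1 -> systole -> S2 -> diastole). L is the T x 4 emission log-likelihood
// matrix at the envelope rate; dur is a list of four per-state duration
// log-probability vectors (index d = duration in frames). The first and last
// segments may be truncated: their duration prior is the running maximum of
// the tail of the duration distribution, so a partially observed state is
// never penalized for the unobserved part of its duration.
// [[Rcpp::export]]
List hsmm_viterbi_cpp(const arma::mat& L, List dur) {
  const int T = L.n_rows;
  if (L.n_cols != 4) stop("emission matrix must have 4 state columns");
  std::vector<arma::vec> dlog(4), dtail(4);
  for (int s = 0; s < 4; ++s) {
    arma::vec v = as<arma::vec>(dur[s]);
    dlog[s] = v;
    arma::vec t(v.n_elem);
    double m = -arma::datum::inf;
    for (int d = (int)v.n_elem - 1; d >= 0; --d) { m = std::max(m, v(d)); t(d) = m; }
    dtail[s] = t;
  }
  arma::mat cum(T + 1, 4, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < 4; ++s) cum(t + 1, s) = cum(t, s) + L(t, s);

  const double NEG = -1e18;
  arma::mat delta(T + 1, 4); delta.fill(NEG);
  arma::imat bestd(T + 1, 4, arma::fill::zeros);

  for (int t = 1; t <= T; ++t) {
    for (int s = 0; s < 4; ++s) {
      const int prev = (s + 3) % 4;
      const int Dsup = (int)dlog[s].n_elem;
      const int Dmax = std::min(Dsup, t);
      double best = NEG; int bd = 0;
      for (int d = 1; d <= Dmax; ++d) {
        const double em = cum(t, s) - cum(t - d, s);
        double sc;
        if (d == t) {
          sc = em + dtail[s](d - 1);      // truncated first segment
        } else {
          if (delta(t - d, prev) <= NEG / 2) continue;
          sc = delta(t - d, prev) + dlog[s](d - 1) + em;
        }
        if (sc > best) { best = sc; bd = d; }
      }
      if (t > Dsup) {                      // whole prefix in one state
        const double sc = cum(t, s) + dtail[s](Dsup - 1);
        if (sc > best) { best = sc; bd = t; }
      }
      delta(t, s) = best; bestd(t, s) = bd;
    }
  }

  double best = NEG; int bs = 0, bd = 0;
  for (int s = 0; s < 4; ++s) {
    const int prev = (s + 3) % 4;
    const int Dsup = (int)dlog[s].n_elem;
    for (int d = 1; d <= T; ++d) {
      const double em = cum(T, s) - cum(T - d, s);
      const double pr = dtail[s](std::min(d, Dsup) - 1);
      double sc;
      if (d == T) {
        sc = em + pr;
      } else {
        if (delta(T - d, prev) <= NEG / 2) continue;
        sc = delta(T - d, prev) + pr + em;
      }
      if (sc > best) { best = sc; bs = s; bd = d; }
    }
  }

  IntegerVector states(T);
  int t = T, s = bs, d = bd;
  bool last = true;
  while (t > 0) {
    if (!last) d = bestd(t, s);
    for (int u = t - d; u < t; ++u) states[u] = s + 1;
    t -= d; s = (s + 3) % 4; last = false;
  }
  return List::create(_["states"] = states, _["log_prob"] = best);
}
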