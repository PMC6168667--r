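// Natural-gradient logistic Infomax ICA weight estimation.
// Operates on pre-sphered data; annealing schedule and stopping rule follow
// the classic runica implementation: block updates over a shuffled sample
// order, learning rate annealed when the update direction turns by more than
// 60 degrees, restart with a smaller rate on blow-up, stop when the squared
// weight change falls below `tol` or after `max_iter` steps.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Clamped Pade approximation of tanh (error < 1e-5 on the unclamped range);
// the logistic score 1 - 2*sigmoid(u) = -tanh(u/2) tolerates this easily and
// it avoids ~1e8 libm calls per decomposition.
static inline double fast_tanh(double x) {
  if (x > 4.97) return 1.0;
  if (x < -4.97) return -1.0;
  const double x2 = x * x;
  const double p = x * (135135.0 + x2 * (17325.0 + x2 * (378.0 + x2)));
  const double q = 135135.0 + x2 * (62370.0 + x2 * (3150.0 + x2 * 28.0));
  return p / q;
}

// [[Rcpp::export]]
Rcpp::List infomax_weights(const arma::mat& X, int seed, int max_iter,
                           double tol, double lrate0) {
  const uword ch = X.n_rows, n = X.n_cols;
  const uword block = (uword) std::ceil(std::min(5.0 * std::log((double) n),
                                                 0.3 * (double) n));
  mat W = eye<mat>(ch, ch);
  double lrate = lrate0;
  double change = datum::inf, oldchange = 0.0;
  mat olddelta;
  std::mt19937 rng((unsigned) seed);
  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;
  const double deg60 = std::cos(60.0 * datum::pi / 180.0);
  int step = 0, restarts = 0;
  mat oldW = W;
  mat Xs(ch, n), u(ch, block), g(ch, block), M(ch, ch), WM(ch, ch);

  while (step < max_iter) {
    std::shuffle(perm.begin(), perm.end(), rng);
    for (uword j = 0; j < n; ++j) Xs.col(j) = X.col(perm[j]);
    bool blowup = false;
    for (uword t = 0; t + block <= n; t += block) {
      u = W * Xs.cols(t, t + block - 1);
      // g = 1 - 2*logistic(u) = -tanh(u/2)
      for (uword j = 0; j < u.n_elem; ++j) g(j) = -fast_tanh(0.5 * u(j));
      M = g * u.t();
      M.diag() += (double) block;
      WM = M * W;
      W += lrate * WM;
      if (W.has_nan() || abs(W).max() > 1e8) { blowup = true; break; }
    }
    if (blowup) {
      if (++restarts > 20) Rcpp::stop("Infomax diverged after 20 restarts");
      W = eye<mat>(ch, ch);
      oldW = W;
      olddelta.reset();
      lrate *= 0.5;
      step = 0;
      change = datum::inf;
      continue;
    }
    ++step;
    mat delta = W - oldW;
    change = accu(delta % delta);
    if (olddelta.n_elem > 0 && change > 0 && oldchange > 0) {
      double cosang = accu(delta % olddelta) / std::sqrt(change * oldchange);
      if (cosang < deg60) lrate *= 0.98;  // direction turned > 60 degrees
    }
    olddelta = delta;
    oldchange = change;
    oldW = W;
    if (change < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("iterations") = step,
                            Rcpp::Named("final_change") = change,
                            Rcpp::Named("lrate") = lrate);
}
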