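// Logistic deviance gains for every subset of up to 12 predictors.
// Hot path of the hierarchical partitioning: 2^K tiny Newton fits per
// partition, repeated for every randomization replicate. The R-level
// gofFit() implements the same estimator independently and is what the
// test oracles call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double subset_dev(const mat& X, const vec& y, double null_dev,
                         double b0) {
  const uword n = X.n_rows, p = X.n_cols;
  vec beta(p, fill::zeros);
  beta(0) = b0;
  vec eta = X * beta;
  double dev = null_dev;
  for (int it = 0; it < 25; ++it) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    mat H = X.t() * (X.each_col() % w);
    H.diag() += 1e-12;              // guard against exact singularity
    vec g = X.t() * (y - mu);
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx)) break;
    vec new_beta = beta + step;
    vec new_eta = X * new_beta;
    vec mu2 = clamp(1.0 / (1.0 + exp(-new_eta)), 1e-12, 1.0 - 1e-12);
    double new_dev = -2.0 * accu(y % log(mu2) + (1.0 - y) % log(1.0 - mu2));
    int half = 0;
    while (new_dev > dev + 1e-10 && half < 10) {   // step halving safeguard
      step *= 0.5;
      new_beta = beta + step;
      new_eta = X * new_beta;
      mu2 = clamp(1.0 / (1.0 + exp(-new_eta)), 1e-12, 1.0 - 1e-12);
      new_dev = -2.0 * accu(y % log(mu2) + (1.0 - y) % log(1.0 - mu2));
      ++half;
    }
    bool done = std::fabs(dev - new_dev) < 1e-9;
    beta = new_beta;
    eta = new_eta;
    dev = new_dev;
    if (done) break;
  }
  return dev;
}

// [[Rcpp::export]]
Rcpp::NumericVector subset_gofs_cpp(const arma::mat& x,
                                    const arma::vec& y) {
  const uword K = x.n_cols;
  const uword n = x.n_rows;
  const uword nsub = 1u << K;
  Rcpp::NumericVector out(nsub);
  double p0 = mean(y);
  if (p0 <= 0.0 || p0 >= 1.0) return out;   // degenerate response
  double null_dev = -2.0 * accu(y * std::log(p0) +
                                (1.0 - y) * std::log(1.0 - p0));
  double b0 = std::log(p0 / (1.0 - p0));
  for (uword mask = 1; mask < nsub; ++mask) {
    uword k = 0;
    for (uword j = 0; j < K; ++j) if (mask & (1u << j)) ++k;
    mat X(n, k + 1);
    X.col(0).ones();
    uword c = 1;
    for (uword j = 0; j < K; ++j)
      if (mask & (1u << j)) X.col(c++) = x.col(j);
    double dev = subset_dev(X, y, null_dev, b0);
    double gain = null_dev - dev;
    out[mask] = gain > 0.0 ? gain : 0.0;
  }
  return out;
}
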