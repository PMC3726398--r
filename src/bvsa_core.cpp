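// Marginal configuration score and componentwise Gibbs kernel.
//
// The score is the closed form of the per-subnetwork marginal posterior of a
// binary regulator configuration, after integrating out the connection
// coefficients (ridge-stabilized g-prior slab), the noise variance
// (inverse-gamma), and the network sparsity (Beta-Bernoulli).  A pure-R
// reference implementation lives in R/marginal.R; tests pin the two together.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log Beta-Bernoulli marginal prior of a configuration with k present edges
// among n-1 candidates: log[ B(a+k, b+n-1-k) / B(a,b) ]
static double log_prior_k(int k, int n, double a, double b) {
  return R::lbeta(a + k, b + (n - 1) - k) - R::lbeta(a, b);
}

// Unnormalized log marginal posterior of one configuration.
// r: response row of the target node (length n_pi)
// Rpr: (n-1) x n_pi candidate-regulator block
// bits: 0/1 over candidates
// Configuration-independent constants are dropped (identically for all
// configurations of a subproblem).
static double score_config(const vec& r, const mat& Rpr, const ivec& bits,
                           double a, double b, double alpha, double beta,
                           double cc, double lambda) {
  const int m = r.n_elem;            // n_pi
  const int ncand = Rpr.n_rows;      // n - 1
  const int n = ncand + 1;
  const uvec sel = find(bits == 1);
  const int k = sel.n_elem;
  const double rr = dot(r, r);
  const double lp = log_prior_k(k, n, a, b);

  if (k == 0)
    return lp - (alpha + 0.5 * m) * std::log(beta + 0.5 * rr);

  const mat X = Rpr.rows(sel);       // k x m
  const mat G = X * X.t();
  mat Gl = G; Gl.diag() += lambda;   // G + lambda I
  const mat M1 = Gl / cc + G;        // K^{-1} + G, K = c (G + lambda I)^{-1}

  mat cGl, cM1;
  if (!chol(cGl, Gl) || !chol(cM1, M1))
    Rcpp::stop("Cholesky factorization failed in configuration score");

  const double ldGl = 2.0 * sum(log(cGl.diag()));
  const double ldM1 = 2.0 * sum(log(cM1.diag()));
  // -0.5 log|I + c X (G+lambda I)^{-1} X^T| in stable form
  const double ldet = -0.5 * (k * std::log(cc) + ldM1 - ldGl);

  const vec u = X * r;
  const vec z = solve(trimatl(cM1.t()), u);
  const double q = dot(z, z);        // u^T M1^{-1} u
  double b1 = beta + 0.5 * (rr - q);
  if (b1 < beta) b1 = beta;          // guard tiny negative round-off in rr - q

  return lp + ldet - (alpha + 0.5 * m) * std::log(b1);
}

// [[Rcpp::export]]
double cpp_log_marginal(const arma::vec& r, const arma::mat& Rpr,
                        const arma::ivec& bits, double a, double b,
                        double alpha, double beta, double cc, double lambda) {
  return score_config(r, Rpr, bits, a, b, alpha, beta, cc, lambda);
}

// Run one Gibbs chain: nts full sweeps in fixed ascending candidate order,
// recording the configuration and its log score after every sweep.
// Uses R's RNG so set.seed() in the caller controls the draw sequence.
// [[Rcpp::export]]
Rcpp::List cpp_run_chain(const arma::vec& r, const arma::mat& Rpr,
                         const arma::ivec& init, int nts, double a, double b,
                         double alpha, double beta, double cc, double lambda) {
  const int p = Rpr.n_rows;
  ivec cur = init;
  double cur_score = score_config(r, Rpr, cur, a, b, alpha, beta, cc, lambda);

  imat samples(nts, p);
  vec scores(nts);

  for (int t = 0; t < nts; ++t) {
    for (int j = 0; j < p; ++j) {
      ivec other = cur;
      other(j) = 1 - cur(j);
      const double other_score =
        score_config(r, Rpr, other, a, b, alpha, beta, cc, lambda);
      const double lp1 = cur(j) == 1 ? cur_score : other_score;
      const double lp0 = cur(j) == 1 ? other_score : cur_score;
      // P(bit = 1) = p1/(p1+p0), log-sum-exp stabilized
      const double p1 = 1.0 / (1.0 + std::exp(lp0 - lp1));
      const int newbit = (R::unif_rand() < p1) ? 1 : 0;
      if (newbit != cur(j)) {
        cur = other;
        cur_score = other_score;
      }
    }
    for (int j = 0; j < p; ++j) samples(t, j) = cur(j);
    scores(t) = cur_score;
  }

  return Rcpp::List::create(Rcpp::Named("samples") = samples,
                            Rcpp::Named("log_scores") = scores);
}
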