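// EM for the aspect Bernoulli decomposition V = Gamma %*% Beta,
// Y_gf ~ Bernoulli(V_gf).  This is the standard EM for a mixture of
// per-cell Bernoulli sources: the latent indicator Z_gfk picks which
// aspect generated cell (g, f).
//
// E-step responsibilities:
//   Y = 1:  w_gfk = Gamma_gk * Beta_kf / V_gf
//   Y = 0:  w_gfk = Gamma_gk * (1 - Beta_kf) / (1 - V_gf)
// M-step:
//   Gamma_gk <- mean over f of w_gfk          (rows stay on the simplex)
//   Beta_kf  <- sum_g w_gfk * Y_gf / sum_g w_gfk
//
// The responsibilities are never materialized as a G x F x K array.  With
// A = Y / V and B = (1 - Y) / (1 - V), the sufficient statistics collapse
// to matrix products:
//   sum_f w_gfk            = Gamma_gk * [ (A Beta')_gk + (B (1-Beta)')_gk ]
//   sum_g w_gfk * Y_gf     = Beta_kf  * (Gamma' A)_kf
//   sum_g w_gfk            = Beta_kf  * (Gamma' A)_kf
//                            + (1 - Beta_kf) * (Gamma' B)_kf
// so one iteration costs four GEMMs plus elementwise work.
//
// V is clipped into [eps, 1 - eps] before divisions and logs: perfect fits
// drive V to the boundary and Bayes' rule divides by V.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double V_EPS = 1e-12;

static inline mat clip01(mat V) {
  return clamp(std::move(V), V_EPS, 1.0 - V_EPS);
}

// One complete EM run from a given initialization.
// Returns the updated parameters, the per-iteration log-likelihood trace
// (evaluated after each update), and whether the relative-change rule fired.
// [[Rcpp::export]]
Rcpp::List ab_em_run(const arma::mat& Y, arma::mat gamma, arma::mat beta,
                     int n_iter, double tol) {
  const uword G = Y.n_rows, F = Y.n_cols, K = gamma.n_cols;
  if (beta.n_rows != K || beta.n_cols != F || gamma.n_rows != G)
    Rcpp::stop("dimension mismatch between Y, gamma and beta");

  const mat Yc = 1.0 - Y;
  std::vector<double> trace;
  trace.reserve(n_iter);
  double ll_prev = -datum::inf;
  bool converged = false;
  int it = 0;

  for (it = 0; it < n_iter; ++it) {
    mat V = clip01(gamma * beta);
    const mat A = Y / V;            // Y = 1 cells: 1 / V
    const mat B = Yc / (1.0 - V);   // Y = 0 cells: 1 / (1 - V)

    // Gamma update: responsibilities averaged over functions
    mat gnew = gamma % (A * beta.t() + B * (1.0 - beta).t()) / double(F);
    gnew.each_col() /= sum(gnew, 1);  // remove float drift off the simplex

    // Beta update: responsibility-weighted presence frequency
    const mat GA = gamma.t() * A;
    const mat GB = gamma.t() * B;
    const mat num = beta % GA;
    const mat den = num + (1.0 - beta) % GB;
    mat bnew(K, F);
    for (uword j = 0; j < num.n_elem; ++j)  // den = 0 only for a dead aspect
      bnew(j) = den(j) > 0.0 ? num(j) / den(j) : beta(j);
    bnew = clamp(std::move(bnew), 0.0, 1.0);

    gamma = std::move(gnew);
    beta = std::move(bnew);

    V = clip01(gamma * beta);
    double ll = accu(Y % log(V) + Yc % log(1.0 - V));
    if (!std::isfinite(ll))
      Rcpp::stop("log-likelihood became non-finite during EM");
    trace.push_back(ll);

    if (it > 0 &&
        std::fabs(ll - ll_prev) < tol * std::max(1.0, std::fabs(ll_prev))) {
      converged = true;
      ++it;
      break;
    }
    ll_prev = ll;
  }

  return Rcpp::List::create(
      Rcpp::Named("gamma") = gamma,
      Rcpp::Named("beta") = beta,
      Rcpp::Named("loglik_trace") = trace,
      Rcpp::Named("n_iter") = it,
      Rcpp::Named("converged") = converged);
}
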