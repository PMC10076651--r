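// Blockwise coordinate-descent graphical lasso (Friedman-style).
// Solves max_Theta  log det(Theta) - tr(S Theta) - rho * sum_{i != j} |Theta_ij|
// with an unpenalized diagonal, by lasso regressions on the columns of the
// working covariance W.  Exact zeros in the lasso coefficients propagate to
// exact zeros in Theta, so edge counts are not inflated by float noise.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One lasso sub-problem for column j:
//   min_beta 0.5 beta' W11 beta - beta' s12 + rho |beta|_1
// beta lives in column j of B (entry (j,j) stays 0).
static void lasso_column(const mat& S, const mat& W, mat& B, uword j,
                         double rho, double thr, int max_inner) {
  const uword p = S.n_rows;
  for (int it = 0; it < max_inner; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      // gradient residual excluding coordinate k (B(j,j) == 0 keeps l == j out)
      double fit = dot(W.row(k), B.col(j)) - W(k, k) * B(k, j);
      double bnew = soft_threshold(S(k, j) - fit, rho) / W(k, k);
      double d = std::abs(bnew - B(k, j));
      if (d > dmax) dmax = d;
      B(k, j) = bnew;
    }
    if (dmax < thr) break;
  }
}

// Single-penalty fit with warm starts.  Returns Theta, W, B and diagnostics.
static void glasso_one(const mat& S, double rho, int maxit, double tol,
                       mat& W, mat& B, mat& Theta, int& niter, bool& converged) {
  const uword p = S.n_rows;
  double off_mean = 0.0;
  if (p > 1) {
    off_mean = (accu(abs(S)) - accu(abs(S.diag()))) / double(p * (p - 1));
  }
  double thr = tol * (off_mean > 0 ? off_mean : 1.0);

  // diagonal is unpenalized: W_jj fixed at S_jj
  W.diag() = S.diag();

  converged = false;
  niter = 0;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      lasso_column(S, W, B, j, rho, thr, 500);
      // w12 <- W11 beta
      vec u = W * B.col(j);
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::abs(u(k) - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = u(k);
        W(j, k) = u(k);
      }
    }
    niter = it + 1;
    if (dmax < thr) { converged = true; break; }
  }

  // Recover Theta from the regression coefficients.
  Theta.zeros(p, p);
  vec tdiag(p);
  for (uword j = 0; j < p; ++j) {
    double denom = W(j, j) - dot(W.col(j), B.col(j));
    tdiag(j) = 1.0 / denom;
  }
  for (uword j = 0; j < p; ++j) {
    Theta(j, j) = tdiag(j);
    for (uword k = j + 1; k < p; ++k) {
      bool zjk = (B(k, j) == 0.0) && (B(j, k) == 0.0);
      if (zjk) continue;
      double v = 0.5 * (-B(k, j) * tdiag(j) - B(j, k) * tdiag(k));
      Theta(k, j) = v;
      Theta(j, k) = v;
    }
  }
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      int maxit = 200, double tol = 1e-4) {
  const uword p = S.n_rows;
  mat W = S, B(p, p, fill::zeros), Theta;
  int niter; bool converged;
  glasso_one(S, rho, maxit, tol, W, B, Theta, niter, converged);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("niter") = niter,
                            Rcpp::Named("converged") = converged);
}

// Descending penalty path with warm starts; returns one Theta per penalty.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           int maxit = 200, double tol = 1e-4) {
  const uword nl = lambdas.n_elem;
  const uword p = S.n_rows;
  mat W = S, B(p, p, fill::zeros), Theta;
  Rcpp::List thetas(nl);
  Rcpp::IntegerVector iters(nl);
  Rcpp::LogicalVector conv(nl);
  for (uword i = 0; i < nl; ++i) {
    int niter; bool converged;
    glasso_one(S, lambdas(i), maxit, tol, W, B, Theta, niter, converged);
    thetas[i] = Theta;
    iters[i] = niter;
    conv[i] = converged;
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("niter") = iters,
                            Rcpp::Named("converged") = conv);
}
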