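// Alternating minimization for the constrained bilinear ("structured") lasso
//
//   min_{alpha, beta} (1/n) sum_i (y_i - alpha' X_i beta)^2 + lambda ||beta||_1
//   s.t. ||alpha||_1 = 1,  sign of the largest-|.| component of beta = +1
//
// beta-step: with alpha fixed, z_i = X_i' alpha gives an ordinary lasso in
// beta, solved by cyclic coordinate descent on the Gram matrix.
// alpha-step: with beta fixed, v_i = X_i beta; since any (alpha, beta) is
// equivalent to (alpha/s, beta*s) with s = ||alpha||_1, profiling the
// constrained objective over this scale class gives
//   min_alpha (1/n)||y - V alpha||^2 + (lambda ||beta||_1) ||alpha||_1,
// an L1 problem in alpha whose penalty weight comes purely from the
// reparametrization (the row effects carry no regularization of their own).
// The pair is then renormalized so ||alpha||_1 = 1 (rescaling beta by the
// same factor, leaving both alpha' X beta and the penalty value unchanged),
// which keeps the objective non-increasing across iterations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static double objective(const cube& X, const vec& y, const vec& alpha,
                        const vec& beta, double lambda) {
  const uword n = X.n_slices;
  double rss = 0.0;
  for (uword i = 0; i < n; ++i) {
    double fit = dot(alpha, X.slice(i) * beta);
    double r = y(i) - fit;
    rss += r * r;
  }
  return rss / (double)n + lambda * accu(abs(beta));
}

// cyclic coordinate descent for min (1/n)||y - Z b||^2 + lambda ||b||_1
static void lasso_cd(const mat& Gram, const vec& lin, double lambda, vec& beta,
                     double tol, int max_pass) {
  const uword q = beta.n_elem;
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_delta = 0.0;
    for (uword j = 0; j < q; ++j) {
      double a = Gram(j, j);
      if (a <= 0.0) { beta(j) = 0.0; continue; }
      double cj = lin(j) - dot(Gram.col(j), beta) + a * beta(j);
      double bj = soft(cj, lambda) / a;
      double d = std::abs(bj - beta(j));
      if (d > max_delta) max_delta = d;
      beta(j) = bj;
    }
    if (max_delta < tol) break;
  }
}

// [[Rcpp::export]]
Rcpp::List solve_single_cpp(const arma::cube& X, const arma::vec& y,
                            double lambda, arma::vec alpha, arma::vec beta,
                            double tol, int max_iter,
                            double cd_tol, int cd_max_pass) {
  const uword n = X.n_slices, G = X.n_rows, q = X.n_cols;
  if (y.n_elem != n) Rcpp::stop("y length does not match number of design slices");
  if (alpha.n_elem != G || beta.n_elem != q) Rcpp::stop("init dimensions do not match design");

  double s = accu(abs(alpha));
  if (s <= 0.0) Rcpp::stop("initial alpha has zero L1 norm");
  alpha /= s; beta *= s;

  double obj = objective(X, y, alpha, beta, lambda);
  std::vector<double> trace;
  trace.push_back(obj);

  bool converged = false;
  int iter = 0;
  mat Z(n, q), V(n, G);

  for (iter = 1; iter <= max_iter; ++iter) {
    // beta-step
    for (uword i = 0; i < n; ++i) Z.row(i) = (X.slice(i).t() * alpha).t();
    mat Gram = (2.0 / n) * (Z.t() * Z);
    vec lin = (2.0 / n) * (Z.t() * y);
    lasso_cd(Gram, lin, lambda, beta, cd_tol, cd_max_pass);

    // alpha-step (skip if beta vanished: V would be identically zero)
    double b_l1 = accu(abs(beta));
    if (b_l1 > 0.0) {
      for (uword i = 0; i < n; ++i) V.row(i) = (X.slice(i) * beta).t();
      mat GramA = (2.0 / n) * (V.t() * V);
      vec linA = (2.0 / n) * (V.t() * y);
      if (rank(GramA) < G) Rcpp::stop("degenerate alpha-step: normal matrix has rank < G");
      vec alpha_prev = alpha;
      lasso_cd(GramA, linA, lambda * b_l1, alpha, cd_tol, cd_max_pass);
      if (accu(abs(alpha)) <= 0.0) {
        // profiled alpha shrank to zero: the equivalent canonical solution
        // has beta = 0 with alpha (any unit vector) left at its last value
        beta.zeros();
        alpha = alpha_prev;
      }
    }

    s = accu(abs(alpha));
    if (s <= 0.0) Rcpp::stop("alpha collapsed to zero L1 norm; restart advised");
    alpha /= s; beta *= s;

    double obj_new = objective(X, y, alpha, beta, lambda);
    trace.push_back(obj_new);
    double rel = (obj - obj_new) / std::max(std::abs(obj), 1e-12);
    obj = obj_new;
    if (rel < tol && rel > -1e-8) { converged = true; break; }
  }

  // canonicalize: flip both signs if the largest-|.| beta component is negative
  if (accu(abs(beta)) > 0.0) {
    uword jmax = index_max(abs(beta));
    // lowest index wins on exact ties
    double m = std::abs(beta(jmax));
    for (uword j = 0; j < q; ++j) {
      if (std::abs(beta(j)) == m) { jmax = j; break; }
    }
    if (beta(jmax) < 0.0) { beta = -beta; alpha = -alpha; }
  }

  return Rcpp::List::create(
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("trace") = trace);
}
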