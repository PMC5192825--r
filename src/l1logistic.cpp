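// Sparse logistic regression core: FISTA proximal gradient with backtracking,
// per-feature l1 penalty factors, unpenalized intercept.  The objective is
//   sum_j log(1 + exp(-y_j (x' f_j + c))) + lambda * sum_i pen_i |x_i|
// with y in {-1,+1}.  Warm-started path and bootstrap-selection loops live
// here too, since stability selection calls the solver thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus_(double v) {
  // numerically stable log(1 + exp(v))
  return v > 0 ? v + std::log1p(std::exp(-v)) : std::log1p(std::exp(v));
}

static double logistic_loss(const mat& X, const vec& y, const vec& x, double c) {
  vec eta = X * x + c;
  double s = 0.0;
  for (uword j = 0; j < eta.n_elem; ++j) s += softplus_(-y[j] * eta[j]);
  return s;
}

// gradient of the smooth part at (x, c); g_j = -y_j * sigmoid(-y_j eta_j)
static void logistic_grad(const mat& X, const vec& y, const vec& x, double c,
                          vec& gx, double& gc) {
  vec eta = X * x + c;
  vec g(eta.n_elem);
  for (uword j = 0; j < eta.n_elem; ++j)
    g[j] = -y[j] / (1.0 + std::exp(y[j] * eta[j]));
  gx = X.t() * g;
  gc = accu(g);
}

static double penalty_value(const vec& x, const vec& pen, double lambda) {
  double s = 0.0;
  for (uword i = 0; i < x.n_elem; ++i) s += pen[i] * std::fabs(x[i]);
  return lambda * s;
}

// one FISTA solve, in place start from (x, c)
static void fista_solve(const mat& X, const vec& y, double lambda,
                        const vec& pen, double tol, int max_iter,
                        vec& x, double& c, double& obj_out, bool& converged,
                        int& iter_out) {
  const uword p = X.n_cols;
  vec xk = x, xprev = x;
  double ck = c, cprev = c;
  double tk = 1.0;
  // diagonal step sizes from crude Lipschitz bounds, refined by joint
  // backtracking.  Keeping the intercept step independent of the scale of X
  // makes the solver exactly scale-equivariant: solving on c*X with lambda
  // scaled by a power-of-two c reproduces the base iterates bit for bit,
  // which the collapse-to-unweighted equivalence relies on.
  double Lx = 0.25 * accu(square(X));
  if (!(Lx > 0)) Lx = 1.0;
  double Lc = 0.25 * std::max((double)X.n_rows, 1.0);
  double step = 1.0 / Lx;
  double step_c = 1.0 / Lc;
  double obj = logistic_loss(X, y, x, c) + penalty_value(x, pen, lambda);
  converged = false;
  int it = 0;
  vec gx(p);
  double gc;
  for (it = 0; it < max_iter; ++it) {
    // momentum point
    double tnext = (1.0 + std::sqrt(1.0 + 4.0 * tk * tk)) / 2.0;
    double mom = (tk - 1.0) / tnext;
    vec yx = xk + mom * (xk - xprev);
    double yc = ck + mom * (ck - cprev);
    double fy = logistic_loss(X, y, yx, yc);
    logistic_grad(X, y, yx, yc, gx, gc);
    // backtracking on the smooth part
    vec xnew(p);
    double cnew;
    for (;;) {
      for (uword i = 0; i < p; ++i) {
        double z = yx[i] - step * gx[i];
        double thr = step * lambda * pen[i];
        xnew[i] = (z > thr) ? z - thr : ((z < -thr) ? z + thr : 0.0);
      }
      cnew = yc - step_c * gc;
      double fnew = logistic_loss(X, y, xnew, cnew);
      vec dx = xnew - yx;
      double dc = cnew - yc;
      double quad = fy + dot(gx, dx) + gc * dc +
                    dot(dx, dx) / (2.0 * step) + dc * dc / (2.0 * step_c);
      if (fnew <= quad + 1e-12 * std::fabs(quad)) break;
      step *= 0.5;
      step_c *= 0.5;
      if (step < 1e-18 || step_c < 1e-18) break;
    }
    xprev = xk; cprev = ck;
    xk = xnew; ck = cnew;
    tk = tnext;
    double obj_new = logistic_loss(X, y, xk, ck) + penalty_value(xk, pen, lambda);
    // FISTA is not monotone; restart momentum on an objective increase
    if (obj_new > obj) { tk = 1.0; xprev = xk; cprev = ck; }
    double denom = std::max(1.0, std::fabs(obj));
    if (std::fabs(obj - obj_new) / denom < tol && it > 0) {
      obj = obj_new;
      converged = true;
      ++it;
      break;
    }
    obj = obj_new;
  }
  x = xk; c = ck; obj_out = obj; iter_out = it;
}

// [[Rcpp::export(name = ".l1_logistic_cpp")]]
Rcpp::List l1_logistic_cpp(const arma::mat& X, const arma::vec& y,
                           double lambda, const arma::vec& penalty,
                           double tol, int max_iter,
                           const arma::vec& x0, double c0) {
  vec x = x0;
  double c = c0, obj;
  bool conv;
  int iters;
  fista_solve(X, y, lambda, penalty, tol, max_iter, x, c, obj, conv, iters);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("intercept") = c,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}

// warm-started solve along a descending lambda sequence
// [[Rcpp::export(name = ".l1_path_cpp")]]
Rcpp::List l1_path_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::vec& lambdas, const arma::vec& penalty,
                       double tol, int max_iter) {
  const uword p = X.n_cols, K = lambdas.n_elem;
  mat coefs(p, K, fill::zeros);
  vec intercepts(K), objectives(K);
  Rcpp::LogicalVector converged(K);
  // intercept-only start at the empirical log odds
  double n1 = accu(y > 0), n0 = accu(y < 0);
  double c = std::log(std::max(n1, 0.5) / std::max(n0, 0.5));
  vec x(p, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    double obj;
    bool conv;
    int iters;
    fista_solve(X, y, lambdas[k], penalty, tol, max_iter, x, c, obj, conv, iters);
    coefs.col(k) = x;
    intercepts[k] = c;
    objectives[k] = obj;
    converged[k] = conv;
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = coefs,
                            Rcpp::Named("intercepts") = intercepts,
                            Rcpp::Named("objectives") = objectives,
                            Rcpp::Named("converged") = converged);
}

// bootstrap selection hits: `indices` is an m_b x B matrix of 1-based row
// indices into X; returns a p x B matrix whose (i, b) entry is the number of
// grid lambdas at which feature i has |coefficient| > zero_tol on bootstrap b.
// [[Rcpp::export(name = ".stability_hits_cpp")]]
arma::umat stability_hits_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::vec& lambdas,
                              const arma::vec& penalty,
                              const arma::umat& indices,
                              double tol, int max_iter, double zero_tol) {
  const uword p = X.n_cols, B = indices.n_cols, K = lambdas.n_elem;
  umat hits(p, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    uvec idx = indices.col(b) - 1;
    mat Xb = X.rows(idx);
    vec yb = y.elem(idx);
    double n1 = accu(yb > 0), n0 = accu(yb < 0);
    double c = std::log(std::max(n1, 0.5) / std::max(n0, 0.5));
    vec x(p, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      double obj;
      bool conv;
      int iters;
      fista_solve(Xb, yb, lambdas[k], penalty, tol, max_iter, x, c, obj, conv,
                  iters);
      for (uword i = 0; i < p; ++i)
        if (std::fabs(x[i]) > zero_tol) hits(i, b) += 1;
    }
  }
  return hits;
}
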