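// EM core for the concomitant-covariate latent class regression model.
//
// Model: P(y | zc, zp) = sum_k pi_k(zc; gamma) * f(y | k, zp; beta_k)
// with pi a (K-class) multinomial logit on the covariates (class K is the
// reference) and f a (C-class) multinomial logit on the predictors within
// each class (category C in the *internal* column order is the reference).
//
// Internal outcome column order is (non-violent, violent, no) so that a
// single Newton routine with reference-last can serve both the membership
// (gamma) and the within-class outcome (beta) maximisations.  The R
// wrappers own the external order (no, non-violent, violent).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Row-wise log-softmax of an N x C linear predictor matrix.
static mat row_log_softmax(const mat& eta) {
  vec m = max(eta, 1);
  mat cen = eta.each_col() - m;
  vec lse = log(sum(exp(cen), 1));
  return cen.each_col() - lse;
}

// Weighted multinomial-logit objective: sum_i w_i sum_j T_ij log p_ij(B)
// with reference category last (zero linear predictor).  T rows are
// fractional targets summing to 1; w are non-negative case weights.
static double mlogit_obj(const mat& X, const mat& T, const vec& w, const mat& B) {
  const uword C = T.n_cols;
  mat eta(X.n_rows, C, fill::zeros);
  if (B.n_rows > 0) eta.cols(0, B.n_rows - 1) = X * B.t();
  mat lp = row_log_softmax(eta);
  return dot(sum(T % lp, 1), w);
}

// Newton maximisation of the weighted multinomial-logit objective with a
// ridge on the Hessian diagonal (quasi-separation guard) and step halving.
// Probabilities are computed once per accepted iterate and shared between
// the objective, gradient and Hessian.
static mat mlogit_newton(const mat& X, const mat& T, const vec& w, mat B,
                         double ridge, int maxit, double tol) {
  const uword P = X.n_cols, Cm1 = T.n_cols - 1;
  if (Cm1 == 0) return B;
  mat eta(X.n_rows, T.n_cols, fill::zeros);
  eta.cols(0, Cm1 - 1) = X * B.t();
  mat lp = row_log_softmax(eta);
  double f = dot(sum(T % lp, 1), w);
  mat Pm = exp(lp);
  vec g(Cm1 * P);
  mat H(Cm1 * P, Cm1 * P);
  for (int it = 0; it < maxit; ++it) {
    for (uword j = 0; j < Cm1; ++j) {
      vec r = w % (T.col(j) - Pm.col(j));
      g.subvec(j * P, (j + 1) * P - 1) = X.t() * r;
    }
    H.zeros();
    for (uword j = 0; j < Cm1; ++j) {
      for (uword l = j; l < Cm1; ++l) {
        vec d = (j == l) ? vec(w % Pm.col(j) % (1.0 - Pm.col(j)))
                         : vec(-(w % Pm.col(j) % Pm.col(l)));
        mat blk = X.t() * (X.each_col() % d);
        H.submat(j * P, l * P, (j + 1) * P - 1, (l + 1) * P - 1) = blk;
        if (l != j)
          H.submat(l * P, j * P, (l + 1) * P - 1, (j + 1) * P - 1) = blk.t();
      }
    }
    H.diag() += ridge;
    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd);
    if (!ok) {
      H.diag() += 1e-6 * (1.0 + H.diag().max());
      if (!solve(step, H, g)) break;
    }
    mat D = reshape(step, P, Cm1).t();
    double alpha = 1.0, fnew = f;
    mat Bnew = B, lp_new = lp;
    bool accepted = false;
    for (int h = 0; h < 40; ++h) {
      Bnew = B + alpha * D;
      eta.cols(0, Cm1 - 1) = X * Bnew.t();
      lp_new = row_log_softmax(eta);
      fnew = dot(sum(T % lp_new, 1), w);
      if (std::isfinite(fnew) && fnew >= f - 1e-12) {
        accepted = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!accepted) break;  // no usable ascent step
    double rel = std::abs(fnew - f) / (std::abs(f) + 1e-10);
    B = Bnew;
    f = fnew;
    lp = lp_new;
    Pm = exp(lp);
    if (rel < tol) break;
  }
  return B;
}

// One-hot outcome targets in the internal (nv, v, no) column order.
static mat outcome_targets(const ivec& y) {
  mat T(y.n_elem, 3, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) {
    int col = (y[i] == 1) ? 0 : (y[i] == 2) ? 1 : 2;
    T(i, col) = 1.0;
  }
  return T;
}

// E-step quantities: returns observed-data log-likelihood; fills the N x K
// posterior matrix W.
static double e_step(const mat& Zc, const mat& Zp, const ivec& y, int K,
                     const mat& gamma, const cube& beta, mat& W) {
  const uword N = Zc.n_rows;
  mat logpi(N, K, fill::zeros);
  if (K > 1) {
    mat eta(N, K, fill::zeros);
    eta.cols(0, K - 2) = Zc * gamma.t();
    logpi = row_log_softmax(eta);
  }
  mat logf(N, K);
  for (int k = 0; k < K; ++k) {
    mat etaB(N, 3, fill::zeros);
    etaB.cols(0, 1) = Zp * beta.slice(k).t();
    mat lp = row_log_softmax(etaB);
    for (uword i = 0; i < N; ++i) {
      int col = (y[i] == 1) ? 0 : (y[i] == 2) ? 1 : 2;
      logf(i, k) = lp(i, col);
    }
  }
  mat joint = logpi + logf;
  vec m = max(joint, 1);
  vec lse = m + log(sum(exp(joint.each_col() - m), 1));
  W = exp(joint.each_col() - lse);
  return accu(lse);
}

// [[Rcpp::export]]
Rcpp::List em_lcra_cpp(const arma::mat& Zc, const arma::mat& Zp,
                       const arma::ivec& y, int K,
                       arma::mat gamma, arma::cube beta,
                       int maxit, double tol, double ridge,
                       int mstep_maxit, double mstep_tol) {
  const uword N = Zc.n_rows;
  mat W(N, K);
  mat Ty = outcome_targets(y);
  vec ones_n(N, fill::ones);
  std::vector<double> trace;
  trace.reserve(maxit);
  double ll_old = -datum::inf;
  bool converged = false;
  int iters = 0;
  for (int it = 0; it < maxit; ++it) {
    double ll = e_step(Zc, Zp, y, K, gamma, beta, W);
    trace.push_back(ll);
    iters = it + 1;
    if (it > 0 &&
        std::abs(ll - ll_old) < tol * (std::abs(ll_old) + 1e-10)) {
      converged = true;
      break;
    }
    ll_old = ll;
    if (K > 1)
      gamma = mlogit_newton(Zc, W, ones_n, gamma, ridge, mstep_maxit, mstep_tol);
    for (int k = 0; k < K; ++k)
      beta.slice(k) =
          mlogit_newton(Zp, Ty, W.col(k), beta.slice(k), ridge, mstep_maxit,
                        mstep_tol);
  }
  double ll_final = e_step(Zc, Zp, y, K, gamma, beta, W);
  return Rcpp::List::create(
      Rcpp::Named("gamma") = gamma, Rcpp::Named("beta") = beta,
      Rcpp::Named("loglik") = ll_final, Rcpp::Named("trace") = trace,
      Rcpp::Named("posteriors") = W, Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iters);
}

// Quiet EM: parameters in/out, final log-likelihood and convergence only.
static void em_core(const mat& Zc, const mat& Zp, const ivec& y, int K,
                    mat& gamma, cube& beta, int maxit, double tol,
                    double ridge, int mstep_maxit, double mstep_tol,
                    double& ll_out, bool& conv_out) {
  const uword N = Zc.n_rows;
  mat W(N, K);
  mat Ty = outcome_targets(y);
  vec ones_n(N, fill::ones);
  double ll_old = -datum::inf;
  conv_out = false;
  for (int it = 0; it < maxit; ++it) {
    double ll = e_step(Zc, Zp, y, K, gamma, beta, W);
    if (it > 0 &&
        std::abs(ll - ll_old) < tol * (std::abs(ll_old) + 1e-10)) {
      conv_out = true;
      ll_out = ll;
      return;
    }
    ll_old = ll;
    if (K > 1)
      gamma = mlogit_newton(Zc, W, ones_n, gamma, ridge, mstep_maxit, mstep_tol);
    for (int k = 0; k < K; ++k)
      beta.slice(k) =
          mlogit_newton(Zp, Ty, W.col(k), beta.slice(k), ridge, mstep_maxit,
                        mstep_tol);
  }
  ll_out = e_step(Zc, Zp, y, K, gamma, beta, W);
}

// One EM run from a random per-case Dirichlet(1) posterior (R RNG).
static void em_random_start(const mat& Zc, const mat& Zp, const ivec& y,
                            int K, int maxit, double tol, double ridge,
                            int mstep_maxit, double mstep_tol,
                            double& ll_out, bool& conv_out) {
  const uword N = Zc.n_rows;
  mat W0(N, K);
  for (uword i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      W0(i, k) = R::exp_rand();
      s += W0(i, k);
    }
    W0.row(i) /= s;
  }
  vec ones_n(N, fill::ones);
  mat gamma(std::max(K - 1, 0), Zc.n_cols, fill::zeros);
  if (K > 1) gamma = mlogit_newton(Zc, W0, ones_n, gamma, ridge, 30, 1e-9);
  mat Ty = outcome_targets(y);
  cube beta(2, Zp.n_cols, K, fill::zeros);
  for (int k = 0; k < K; ++k)
    beta.slice(k) = mlogit_newton(Zp, Ty, W0.col(k),
                                  mat(2, Zp.n_cols, fill::zeros), ridge, 30,
                                  1e-9);
  em_core(Zc, Zp, y, K, gamma, beta, maxit, tol, ridge, mstep_maxit,
          mstep_tol, ll_out, conv_out);
}

static void best_of_restarts(const mat& Zc, const mat& Zp, const ivec& y,
                             int K, int restarts, int maxit, double tol,
                             double ridge, int mstep_maxit, double mstep_tol,
                             double& best_ll, bool& best_conv) {
  int R = (K == 1) ? 1 : restarts;
  best_ll = -datum::inf;
  best_conv = false;
  for (int r = 0; r < R; ++r) {
    double ll;
    bool conv;
    em_random_start(Zc, Zp, y, K, maxit, tol, ridge, mstep_maxit, mstep_tol,
                    ll, conv);
    if (ll > best_ll) {
      best_ll = ll;
      best_conv = conv;
    }
  }
}

// Parametric-bootstrap engine for the likelihood-ratio test between two
// nested class counts.  Replicate 0 is the observed outcome vector; each
// of the B further replicates draws outcomes from the per-case cumulative
// mixture probabilities `cumP` (from the fitted small model).  Both
// models are refitted on every replicate with the identical procedure
// (same restarts, iteration cap and tolerances), so the observed and
// replicate statistics are exchangeable under the null.  Uses R's RNG:
// seed with set.seed() on the R side.
// [[Rcpp::export]]
Rcpp::List boot_lrt_cpp(const arma::mat& Zc1, const arma::mat& Zp1,
                        const arma::ivec& y_obs, const arma::mat& cumP,
                        int B, int K_small, int K_big, int restarts,
                        int maxit, double tol, double ridge,
                        int mstep_maxit, double mstep_tol) {
  const uword N = Zc1.n_rows;
  vec ll_small(B + 1), ll_big(B + 1);
  ivec conv_small(B + 1), conv_big(B + 1);
  ivec y = y_obs;
  for (int b = 0; b <= B; ++b) {
    if (b > 0) {
      for (uword i = 0; i < N; ++i) {
        double u = R::unif_rand();
        int yi = 0;
        while (yi < 2 && u > cumP(i, yi)) ++yi;
        y[i] = yi;
      }
    }
    double lls, llb;
    bool cs, cb;
    best_of_restarts(Zc1, Zp1, y, K_small, restarts, maxit, tol, ridge,
                     mstep_maxit, mstep_tol, lls, cs);
    best_of_restarts(Zc1, Zp1, y, K_big, restarts, maxit, tol, ridge,
                     mstep_maxit, mstep_tol, llb, cb);
    ll_small[b] = lls;
    ll_big[b] = llb;
    conv_small[b] = cs ? 1 : 0;
    conv_big[b] = cb ? 1 : 0;
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("ll_small") = ll_small,
                            Rcpp::Named("ll_big") = ll_big,
                            Rcpp::Named("conv_small") = conv_small,
                            Rcpp::Named("conv_big") = conv_big);
}

// [[Rcpp::export]]
Rcpp::List mlogit_fit_cpp(const arma::mat& X, const arma::mat& T,
                          const arma::vec& w, arma::mat B0, double ridge,
                          int maxit, double tol) {
  mat B = mlogit_newton(X, T, w, B0, ridge, maxit, tol);
  double f = mlogit_obj(X, T, w, B);
  return Rcpp::List::create(Rcpp::Named("coef") = B,
                            Rcpp::Named("objective") = f);
}
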