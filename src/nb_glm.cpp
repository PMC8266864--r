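#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-gene negative-binomial GLM (log link, fixed dispersion, offset) fitted
// by iteratively reweighted least squares with Fisher weights
// w = mu / (1 + alpha * mu).  Counts Y are genes x samples, the design X is
// samples x p and is shared across genes; offset is the per-sample log size
// factor.  Returns natural-log-scale coefficients, asymptotic standard
// errors (sqrt of the diagonal of (X'WX)^-1) and a status code per gene:
// 0 converged, 1 hit the iteration cap, 2 degenerate (all-zero counts).
// [[Rcpp::export]]
List nb_glm_fit_cpp(const arma::mat& Y, const arma::mat& X,
                    const arma::vec& offset, const arma::vec& alpha,
                    int maxit = 100, double tol = 1e-8) {
  const arma::uword G = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  if (offset.n_elem != n) stop("offset length must equal the sample count");
  if (alpha.n_elem != G) stop("alpha length must equal the gene count");

  arma::mat beta(G, p, arma::fill::zeros);
  arma::mat se(G, p);
  se.fill(NA_REAL);
  IntegerVector status(G);

  const arma::mat XtX = X.t() * X;

  for (arma::uword g = 0; g < G; ++g) {
    arma::vec y = Y.row(g).t();
    if (arma::accu(y) == 0.0) {
      status[g] = 2;
      continue;
    }
    double a = alpha[g] > 1e-12 ? alpha[g] : 1e-12;

    // init from a log-linear least-squares fit
    arma::vec z0 = arma::log(y + 0.5) - offset;
    arma::vec b;
    if (!arma::solve(b, XtX, X.t() * z0, arma::solve_opts::fast)) b = arma::zeros(p);

    bool ok = false;
    arma::mat XtWX(p, p);
    for (int it = 0; it < maxit; ++it) {
      arma::vec eta = arma::clamp(X * b + offset, -30.0, 30.0);
      arma::vec mu = arma::exp(eta);
      arma::vec w = mu / (1.0 + a * mu);
      arma::vec z = (eta - offset) + (y - mu) / mu;
      XtWX = X.t() * (X.each_col() % w);
      arma::vec bnew;
      if (!arma::solve(bnew, XtWX, X.t() * (w % z), arma::solve_opts::fast)) break;
      double delta = arma::abs(bnew - b).max();
      b = bnew;
      if (delta < tol) { ok = true; break; }
    }
    beta.row(g) = b.t();
    // observed-information covariance at the final estimate
    arma::vec eta = arma::clamp(X * b + offset, -30.0, 30.0);
    arma::vec mu = arma::exp(eta);
    arma::vec w = mu / (1.0 + a * mu);
    XtWX = X.t() * (X.each_col() % w);
    arma::mat cov;
    if (arma::inv_sympd(cov, XtWX)) {
      se.row(g) = arma::sqrt(cov.diag()).t();
    } else {
      arma::mat covp;
      if (arma::pinv(covp, XtWX)) se.row(g) = arma::sqrt(covp.diag()).t();
    }
    status[g] = ok ? 0 : 1;
  }

  return List::create(Named("beta") = beta, Named("se") = se,
                      Named("status") = status);
}

// IRLS fit for one gene at fixed dispersion; returns true on convergence and
// fills beta (used as warm start) and the weighted information matrix.
static bool irls_one(const arma::vec& y, const arma::mat& X,
                     const arma::vec& offset, double a, arma::vec& b,
                     arma::mat& XtWX, int maxit, double tol) {
  const arma::uword p = X.n_cols;
  bool ok = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = arma::clamp(X * b + offset, -30.0, 30.0);
    arma::vec mu = arma::exp(eta);
    arma::vec w = mu / (1.0 + a * mu);
    arma::vec z = (eta - offset) + (y - mu) / mu;
    XtWX = X.t() * (X.each_col() % w);
    arma::vec bnew;
    if (!arma::solve(bnew, XtWX, X.t() * (w % z), arma::solve_opts::fast)) break;
    double delta = arma::abs(bnew - b).max();
    b = bnew;
    if (delta < tol) { ok = true; break; }
  }
  if (XtWX.n_rows != p) XtWX.eye(p, p);
  return ok;
}

// Cox-Reid adjusted profile log-likelihood for one gene at dispersion a,
// profiling out the coefficients: loglik(beta_hat) - 0.5 * logdet(X'WX)
static double cr_apl(const arma::vec& y, const arma::mat& X,
                     const arma::vec& offset, double a, arma::vec& b_warm) {
  arma::mat XtWX;
  irls_one(y, X, offset, a, b_warm, XtWX, 50, 1e-6);
  arma::vec eta = arma::clamp(X * b_warm + offset, -30.0, 30.0);
  arma::vec mu = arma::exp(eta);
  double size = 1.0 / a;
  double ll = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    ll += R::dnbinom_mu(y[j], size, mu[j], 1);
  }
  double ldet, sign;
  if (!arma::log_det(ldet, sign, XtWX) || sign <= 0) return -1e300;
  return ll - 0.5 * ldet;
}

// Per-gene dispersion by maximizing the Cox-Reid adjusted profile likelihood
// over a log-spaced grid (with a parabolic refinement around the best grid
// point).  Grid values must be increasing.
// [[Rcpp::export]]
NumericVector nb_cr_dispersion_cpp(const arma::mat& Y, const arma::mat& X,
                                   const arma::vec& offset,
                                   const arma::vec& grid) {
  const arma::uword G = Y.n_rows, K = grid.n_elem;
  NumericVector out(G);
  for (arma::uword g = 0; g < G; ++g) {
    arma::vec y = Y.row(g).t();
    if (arma::accu(y) == 0.0) { out[g] = grid[0]; continue; }
    arma::vec z0 = arma::log(y + 0.5) - offset;
    arma::vec b0;
    if (!arma::solve(b0, X.t() * X, X.t() * z0, arma::solve_opts::fast)) {
      b0 = arma::zeros(X.n_cols);
    }
    arma::vec apl(K);
    arma::vec b = b0;
    for (arma::uword k = 0; k < K; ++k) {
      apl[k] = cr_apl(y, X, offset, grid[k], b);
    }
    arma::uword best = apl.index_max();
    double a_hat = grid[best];
    if (best > 0 && best < K - 1) {
      // parabolic interpolation on log(alpha)
      double x0 = std::log(grid[best - 1]), x1 = std::log(grid[best]),
             x2 = std::log(grid[best + 1]);
      double y0 = apl[best - 1], y1 = apl[best], y2 = apl[best + 1];
      double denom = (x1 - x0) * (y1 - y2) - (x1 - x2) * (y1 - y0);
      if (std::fabs(denom) > 1e-12) {
        double xv = x1 - 0.5 * ((x1 - x0) * (x1 - x0) * (y1 - y2) -
                                (x1 - x2) * (x1 - x2) * (y1 - y0)) / denom;
        if (xv > x0 && xv < x2) a_hat = std::exp(xv);
      }
    }
    out[g] = a_hat;
  }
  return out;
}

// Wald statistics for a single design column, for permutation re-fits:
// identical model to nb_glm_fit_cpp but returns only beta/se for column
// `col` (0-based).
// [[Rcpp::export]]
NumericVector nb_glm_wald_cpp(const arma::mat& Y, const arma::mat& X,
                              const arma::vec& offset, const arma::vec& alpha,
                              int col, int maxit = 100, double tol = 1e-8) {
  List fit = nb_glm_fit_cpp(Y, X, offset, alpha, maxit, tol);
  arma::mat beta = fit["beta"];
  arma::mat se = fit["se"];
  IntegerVector status = fit["status"];
  const arma::uword G = Y.n_rows;
  NumericVector w(G);
  for (arma::uword g = 0; g < G; ++g) {
    double s = se(g, col);
    if (status[g] == 2 || NumericVector::is_na(s) || s <= 0.0) {
      w[g] = 0.0;
    } else {
      w[g] = beta(g, col) / s;
    }
  }
  return w;
}
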