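// Negative binomial GLM fitting by IRLS with log link and offsets.
// Dispersion phi parameterizes the variance as mu + phi * mu^2 and is held
// fixed during a fit. Written small and dense on purpose: these routines sit
// inside per-gene, per-variant scan loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MU_FLOOR = 1e-10;

// Unit deviance summed over observations; Poisson branch for phi ~ 0.
static double nb_deviance_cpp(const arma::vec& y, const arma::vec& mu,
                              double phi) {
  double dev = 0.0;
  const arma::uword n = y.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double yi = y[i];
    double mi = std::max(mu[i], MU_FLOOR);
    double t1 = (yi > 0.0) ? yi * std::log(yi / mi) : 0.0;
    double t2;
    if (phi < 1e-12) {
      t2 = -(yi - mi);
    } else {
      t2 = -(yi + 1.0 / phi) * (std::log1p(phi * yi) - std::log1p(phi * mi));
    }
    dev += 2.0 * (t1 + t2);
  }
  return dev;
}

// [[Rcpp::export(name = ".nb_deviance_cpp")]]
double nb_deviance_export(const arma::vec& y, const arma::vec& mu,
                          double phi) {
  return nb_deviance_cpp(y, mu, phi);
}

struct NbFit {
  arma::vec beta;
  arma::vec mu;
  double dev;
  int iter;
  bool conv;
};

// One IRLS fit at fixed dispersion. X must be full column rank (the R
// wrapper drops aliased columns first). Step-halving guards against
// deviance increases.
static NbFit nb_irls_one(const arma::vec& y, const arma::mat& X,
                         const arma::vec& offset, double phi, int max_iter,
                         double tol) {
  const arma::uword n = y.n_elem;
  NbFit fit;
  fit.conv = false;
  fit.iter = 0;

  // initialize from shifted response on the log scale
  arma::vec mu0 = y + arma::mean(y) / 6.0 + 0.1;
  arma::vec eta = arma::log(mu0) - offset;
  arma::vec beta;
  {
    // crude LS start for beta so eta = X beta + offset from iteration 1 on
    arma::mat XtX = X.t() * X;
    beta = arma::solve(XtX, X.t() * eta, arma::solve_opts::likely_sympd);
  }
  eta = X * beta + offset;
  arma::vec mu = arma::exp(eta);
  mu.transform([](double v) { return std::max(v, MU_FLOOR); });
  double dev = nb_deviance_cpp(y, mu, phi);

  for (int it = 1; it <= max_iter; ++it) {
    fit.iter = it;
    arma::vec w(n), z(n);
    for (arma::uword i = 0; i < n; ++i) {
      double mi = mu[i];
      w[i] = mi / (1.0 + phi * mi);
      z[i] = (eta[i] - offset[i]) + (y[i] - mi) / mi;
    }
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, XtWz,
                          arma::solve_opts::likely_sympd);
    if (!ok) break;

    // step halving when the deviance goes up
    double dev_new = 0.0;
    arma::vec eta_new, mu_new;
    double frac = 1.0;
    for (int h = 0; h < 12; ++h) {
      arma::vec b_try = beta + frac * (beta_new - beta);
      eta_new = X * b_try + offset;
      mu_new = arma::exp(eta_new);
      mu_new.transform([](double v) { return std::max(v, MU_FLOOR); });
      dev_new = nb_deviance_cpp(y, mu_new, phi);
      if (std::isfinite(dev_new) && dev_new <= dev + 1e-12 * (1.0 + dev)) {
        beta = b_try;
        break;
      }
      frac *= 0.5;
      if (h == 11) {  // no improving step found; accept shortest
        beta = beta + frac * (beta_new - beta);
      }
    }
    eta = eta_new;
    mu = mu_new;
    double change = std::fabs(dev - dev_new) / (std::fabs(dev_new) + 0.1);
    dev = dev_new;
    if (change < tol) {
      fit.conv = true;
      break;
    }
  }
  fit.beta = beta;
  fit.mu = mu;
  fit.dev = dev;
  return fit;
}

// [[Rcpp::export(name = ".nb_irls_cpp")]]
List nb_irls_cpp(const arma::vec& y, const arma::mat& X,
                 const arma::vec& offset, double phi, int max_iter,
                 double tol) {
  NbFit f = nb_irls_one(y, X, offset, phi, max_iter, tol);
  return List::create(_["beta"] = f.beta, _["mu"] = f.mu,
                      _["deviance"] = f.dev, _["iterations"] = f.iter,
                      _["converged"] = f.conv);
}

// Fit every row of Y (genes x samples) against a common design; phi varies
// per gene. Returns per-gene coefficients, fitted means and deviances.
// [[Rcpp::export(name = ".nb_irls_matrix_cpp")]]
List nb_irls_matrix_cpp(const arma::mat& Y, const arma::mat& X,
                        const arma::vec& offset, const arma::vec& phi,
                        int max_iter, double tol) {
  const arma::uword G = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  arma::mat beta(G, p), mu(G, n);
  arma::vec dev(G);
  IntegerVector iters(G);
  LogicalVector conv(G);
  for (arma::uword g = 0; g < G; ++g) {
    NbFit f = nb_irls_one(Y.row(g).t(), X, offset, phi[g], max_iter, tol);
    beta.row(g) = f.beta.t();
    mu.row(g) = f.mu.t();
    dev[g] = f.dev;
    iters[g] = f.iter;
    conv[g] = f.conv;
  }
  return List::create(_["beta"] = beta, _["mu"] = mu, _["deviance"] = dev,
                      _["iterations"] = iters, _["converged"] = conv);
}
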