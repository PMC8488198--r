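#include <Rcpp.h>
using namespace Rcpp;

// One Gauss-Seidel sweep of the mean-field coordinate-ascent updates for the
// summary-statistics model. Coordinates are visited in ascending index order
// and each update uses the freshest means; running products r1 = R1 * mu and
// r2 = R2 * mu are maintained incrementally so a sweep costs O(m^2).
// [[Rcpp::export(name = ".sweep_summary")]]
List sweep_summary(NumericVector z1, NumericVector z2,
                   NumericMatrix R1, NumericMatrix R2,
                   NumericVector mu0, double sigma2, double alphap,
                   double tau) {
  int m = mu0.size();
  NumericVector mu = clone(mu0);
  NumericVector s2(m);
  double t2 = tau * tau, a2 = alphap * alphap;
  std::vector<double> r1(m, 0.0), r2(m, 0.0);
  for (int k = 0; k < m; ++k) {
    double mk = mu[k];
    if (mk != 0.0) {
      for (int l = 0; l < m; ++l) {
        r1[l] += R1(l, k) * mk;
        r2[l] += R2(l, k) * mk;
      }
    }
  }
  for (int k = 0; k < m; ++k) {
    double prec = t2 * R1(k, k) + a2 * R2(k, k) + 1.0 / sigma2;
    double v = 1.0 / prec;
    double lin = tau * z1[k] + alphap * z2[k]
      - t2 * (r1[k] - R1(k, k) * mu[k])
      - a2 * (r2[k] - R2(k, k) * mu[k]);
    double mu_new = v * lin;
    double d = mu_new - mu[k];
    if (d != 0.0) {
      for (int l = 0; l < m; ++l) {
        r1[l] += R1(l, k) * d;
        r2[l] += R2(l, k) * d;
      }
    }
    mu[k] = mu_new;
    s2[k] = v;
  }
  return List::create(_["mu"] = mu, _["s2"] = s2);
}

// Same sweep for the individual-level eQTL arm: the expression likelihood
// y | gamma ~ N(tau * X * gamma, sigma2e * I) enters through XtX and Xty,
// the GWAS arm through z2 and R2 exactly as in the summary model.
// [[Rcpp::export(name = ".sweep_individual")]]
List sweep_individual(NumericVector xty, NumericMatrix xtx, double sigma2e,
                      NumericVector z2, NumericMatrix R2,
                      NumericVector mu0, double sigma2, double alphap,
                      double tau) {
  int m = mu0.size();
  NumericVector mu = clone(mu0);
  NumericVector s2(m);
  double t2 = tau * tau, a2 = alphap * alphap;
  double inv_e = 1.0 / sigma2e;
  std::vector<double> rx(m, 0.0), r2(m, 0.0);
  for (int k = 0; k < m; ++k) {
    double mk = mu[k];
    if (mk != 0.0) {
      for (int l = 0; l < m; ++l) {
        rx[l] += xtx(l, k) * mk;
        r2[l] += R2(l, k) * mk;
      }
    }
  }
  for (int k = 0; k < m; ++k) {
    double prec = t2 * inv_e * xtx(k, k) + a2 * R2(k, k) + 1.0 / sigma2;
    double v = 1.0 / prec;
    double lin = tau * inv_e * xty[k] + alphap * z2[k]
      - t2 * inv_e * (rx[k] - xtx(k, k) * mu[k])
      - a2 * (r2[k] - R2(k, k) * mu[k]);
    double mu_new = v * lin;
    double d = mu_new - mu[k];
    if (d != 0.0) {
      for (int l = 0; l < m; ++l) {
        rx[l] += xtx(l, k) * d;
        r2[l] += R2(l, k) * d;
      }
    }
    mu[k] = mu_new;
    s2[k] = v;
  }
  return List::create(_["mu"] = mu, _["s2"] = s2);
}
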