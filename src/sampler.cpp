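// Adaptive Metropolis-within-Gibbs sampler for Bayesian logistic (daily
// Bernoulli survival) models with independent Normal(0, prior_prec) priors
// on every coefficient, including random-effect levels.
//
// Componentwise Gaussian random-walk proposals; proposal scales adapt only
// during burn-in, targeting a 30-45% acceptance window.  Uses R's RNG so
// draws are reproducible under set.seed() from the calling R session.

#include <Rcpp.h>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli-logit log likelihood: sum_i y_i*eta_i - log(1 + exp(eta_i))
static double loglik(const std::vector<double>& eta, const double* y, int n) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) ll += y[i] * eta[i] - softplus(eta[i]);
  return ll;
}

// Hierarchical intercept/random-effect columns span flat likelihood
// directions (adding d to a parent level and subtracting it from each of
// its child levels leaves every linear predictor unchanged).  `groups`
// lists these directions (first element = parent column, rest = children,
// 0-based); after each sweep the shift d is Gibbs-sampled exactly from its
// Gaussian full conditional, which depends on the prior alone.
static void recenter_move(std::vector<double>& theta, const List& groups,
                          double prior_prec) {
  for (int g = 0; g < groups.size(); ++g) {
    IntegerVector grp = groups[g];
    const int parent = grp[0];
    const int m = grp.size() - 1;
    if (m < 1) continue;
    double sum_child = 0.0;
    for (int k = 1; k <= m; ++k) sum_child += theta[grp[k]];
    const double mean = (sum_child - theta[parent]) / (1.0 + m);
    const double sd = std::sqrt(1.0 / (prior_prec * (1.0 + m)));
    const double d = mean + sd * R::norm_rand();
    theta[parent] += d;
    for (int k = 1; k <= m; ++k) theta[grp[k]] -= d;
  }
}

// [[Rcpp::export]]
List mwg_chain_cpp(NumericMatrix X, NumericVector y, double prior_prec,
                   int n_iter, int burn_in, int thin,
                   NumericVector init, NumericVector init_scale,
                   int adapt_interval, double target_low, double target_high,
                   List groups) {
  const int n = X.nrow(), p = X.ncol();
  if (init.size() != p) stop("init length must match ncol(X)");
  std::vector<double> theta(init.begin(), init.end());
  std::vector<double> scale(p, 1.0);
  for (int j = 0; j < p; ++j)
    scale[j] = (init_scale.size() == p) ? init_scale[j] : 0.5;

  std::vector<double> eta(n, 0.0), eta_prop(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * theta[j];
    eta[i] = e;
  }
  double cur_ll = loglik(eta, REAL(y), n);

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, p);
  std::vector<int> acc_win(p, 0), acc_tot(p, 0);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      const double d = scale[j] * R::norm_rand();
      const double theta_new = theta[j] + d;
      for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + X(i, j) * d;
      const double new_ll = loglik(eta_prop, REAL(y), n);
      const double dprior = -0.5 * prior_prec *
        (theta_new * theta_new - theta[j] * theta[j]);
      if (std::log(R::unif_rand()) < new_ll - cur_ll + dprior) {
        theta[j] = theta_new;
        std::swap(eta, eta_prop);
        cur_ll = new_ll;
        ++acc_win[j];
        ++acc_tot[j];
      }
    }
    if (groups.size() > 0) recenter_move(theta, groups, prior_prec);
    if (it <= burn_in && it % adapt_interval == 0) {
      for (int j = 0; j < p; ++j) {
        const double rate = (double)acc_win[j] / adapt_interval;
        if (rate > target_high) scale[j] *= 1.25;
        else if (rate < target_low) scale[j] *= 0.8;
        if (scale[j] < 1e-5) scale[j] = 1e-5;
        if (scale[j] > 100.0) scale[j] = 100.0;
        acc_win[j] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) draws(kept, j) = theta[j];
      ++kept;
    }
  }

  NumericVector acc_rate(p), scales(p);
  for (int j = 0; j < p; ++j) {
    acc_rate[j] = (double)acc_tot[j] / n_iter;
    scales[j] = scale[j];
  }
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["scales"] = scales);
}
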