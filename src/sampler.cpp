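// Softmax choice log-likelihood and adaptive random-walk Metropolis sampler.
//
// Options of all decision contexts are flattened into parallel arrays:
//   x[i]   weighted own payoff (kJPY)
//   d[i]   weighted disadvantage distance max((y - x)/2, 0) (kJPY)
//   a[i]   weighted advantage distance    max((x - y)/2, 0) (kJPY)
//   ctx[i] 0-based context id, non-decreasing
// chosen[c] is the flat index of the option chosen in context c.
// Utility is linear in (alpha, beta): U = x - alpha*d - beta*a.

#include <Rcpp.h>
using namespace Rcpp;

static double loglik_flat(double alpha, double beta, double lambda,
                          const NumericVector& x, const NumericVector& d,
                          const NumericVector& a, const IntegerVector& ctx,
                          int nctx, const IntegerVector& chosen,
                          std::vector<double>& u) {
  const int n = x.size();
  for (int i = 0; i < n; ++i)
    u[i] = lambda * (x[i] - alpha * d[i] - beta * a[i]);
  double lp = 0.0;
  int i = 0;
  for (int c = 0; c < nctx; ++c) {
    int start = i;
    double m = u[i];
    while (i < n && ctx[i] == c) { if (u[i] > m) m = u[i]; ++i; }
    double s = 0.0;
    for (int j = start; j < i; ++j) s += std::exp(u[j] - m);
    lp += u[chosen[c]] - (m + std::log(s));
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_loglik(double alpha, double beta, double lambda,
                  NumericVector x, NumericVector d, NumericVector a,
                  IntegerVector ctx, int nctx, IntegerVector chosen) {
  std::vector<double> u(x.size());
  return loglik_flat(alpha, beta, lambda, x, d, a, ctx, nctx, chosen, u);
}

// Log posterior on the working scale theta = (alpha, beta, log lambda):
// normal priors on alpha, beta; half-normal on lambda plus the log-scale
// Jacobian term.
static double log_post(const double* th,
                       const NumericVector& x, const NumericVector& d,
                       const NumericVector& a, const IntegerVector& ctx,
                       int nctx, const IntegerVector& chosen,
                       double am, double as, double bm, double bs, double ls,
                       std::vector<double>& u) {
  double lambda = std::exp(th[2]);
  if (!std::isfinite(lambda)) return R_NegInf;
  double lp = loglik_flat(th[0], th[1], lambda, x, d, a, ctx, nctx, chosen, u);
  lp += -0.5 * (th[0] - am) * (th[0] - am) / (as * as);
  lp += -0.5 * (th[1] - bm) * (th[1] - bm) / (bs * bs);
  lp += -0.5 * lambda * lambda / (ls * ls) + th[2];
  return lp;
}

// One chain of component-wise random-walk Metropolis on theta. Proposal
// scales adapt every `adapt_every` iterations during warmup towards an
// acceptance rate of about 0.35, then stay fixed. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_mh_chain(NumericVector init, int n_warmup, int n_keep,
                  NumericVector prop_sd, int adapt_every,
                  NumericVector x, NumericVector d, NumericVector a,
                  IntegerVector ctx, int nctx, IntegerVector chosen,
                  double alpha_mean, double alpha_sd,
                  double beta_mean, double beta_sd, double lambda_sd) {
  RNGScope scope;
  std::vector<double> u(x.size());
  double th[3] = {init[0], init[1], init[2]};
  double sd[3] = {prop_sd[0], prop_sd[1], prop_sd[2]};
  double lp = log_post(th, x, d, a, ctx, nctx, chosen,
                       alpha_mean, alpha_sd, beta_mean, beta_sd, lambda_sd, u);
  NumericMatrix draws(n_keep, 3);
  long acc[3] = {0, 0, 0}, tot[3] = {0, 0, 0};
  int win_acc[3] = {0, 0, 0};
  const int n_iter = n_warmup + n_keep;
  for (int it = 0; it < n_iter; ++it) {
    for (int k = 0; k < 3; ++k) {
      double old = th[k];
      th[k] = old + R::rnorm(0.0, sd[k]);
      double lp_new = log_post(th, x, d, a, ctx, nctx, chosen,
                               alpha_mean, alpha_sd, beta_mean, beta_sd,
                               lambda_sd, u);
      if (std::isfinite(lp_new) &&
          (lp_new >= lp || R::runif(0.0, 1.0) < std::exp(lp_new - lp))) {
        lp = lp_new;
        if (it >= n_warmup) ++acc[k];
        ++win_acc[k];
      } else {
        th[k] = old;
      }
      if (it >= n_warmup) ++tot[k];
    }
    if (it < n_warmup && (it + 1) % adapt_every == 0) {
      for (int k = 0; k < 3; ++k) {
        double rate = win_acc[k] / (double)adapt_every;
        sd[k] *= std::exp(rate - 0.35);
        if (sd[k] < 1e-4) sd[k] = 1e-4;
        if (sd[k] > 10.0) sd[k] = 10.0;
        win_acc[k] = 0;
      }
    }
    if (it >= n_warmup) {
      int r = it - n_warmup;
      draws(r, 0) = th[0];
      draws(r, 1) = th[1];
      draws(r, 2) = th[2];
    }
  }
  NumericVector acc_rate(3), final_sd(3);
  for (int k = 0; k < 3; ++k) {
    acc_rate[k] = tot[k] ? acc[k] / (double)tot[k] : NA_REAL;
    final_sd[k] = sd[k];
  }
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate,
                      _["prop_sd"] = final_sd);
}
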