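#include <Rcpp.h>
using namespace Rcpp;

// Shared trial-by-trial engine for all model families.
//
// Family codes: 1 = reward, 2 = utility (mean-variance), 3 = ssat
// (satisficing probability), 4 = power utility.  Parameter vector layout
// (always length 6, unused slots ignored):
//   par[0] alpha   mean learning rate, (0,1)
//   par[1] beta    softmax inverse temperature, >= 0
//   par[2] gamma   variance learning rate, (0,1)   (utility, ssat)
//   par[3] lambda  risk aversion, > 0              (utility)
//   par[4] thresh  acceptability threshold, (0,1)  (ssat; drift variants)
//   par[5] rho     power-utility exponent, [0,1)   (power)
//
// All beliefs live on the normalized reward scale (points / 100).

static const double V_FLOOR = 1e-6;

struct Par {
  double alpha, beta, gamma, lambda, thresh, rho;
  explicit Par(const NumericVector& p)
    : alpha(p[0]), beta(p[1]), gamma(p[2]), lambda(p[3]),
      thresh(p[4]), rho(p[5]) {}
};

inline double pow_utility(double r, double rho) {
  return std::pow(r, 1.0 - rho) / (1.0 - rho);
}

inline double decision_value(int family, double Q, double V, const Par& p) {
  switch (family) {
  case 1:
  case 4:
    return Q;
  case 2:
    return Q - p.lambda * V / 2.0;
  case 3:
    return R::pnorm((Q - p.thresh) / std::sqrt(V), 0.0, 1.0, 1, 0);
  }
  return NA_REAL;
}

inline void update_chosen(int family, double r, double& Q, double& V,
                          const Par& p) {
  double x = (family == 4) ? pow_utility(r, p.rho) : r;
  double q_old = Q;
  Q += p.alpha * (x - Q);
  if (family == 2 || family == 3) {
    V += p.gamma * ((r - q_old) * (r - q_old) - V);
    if (V < V_FLOOR) V = V_FLOOR;
  }
}

// Replay a fixed sequence of choices and rewards through a model and
// return the per-trial choice log-likelihood and decision variables.
// choice: 1 = good arm, 0 = bad arm; reward on the normalized scale.
// [[Rcpp::export]]
List bandit_replay_cpp(IntegerVector choice, NumericVector reward,
                       int family, bool drift, NumericVector par,
                       double q0, double v0) {
  int n = choice.size();
  Par p(par);
  double Q[2] = {q0, q0}, V[2] = {v0, v0};
  double drift_target = drift ?
    ((family == 4) ? pow_utility(p.thresh, p.rho) : p.thresh) : 0.0;
  NumericVector ll(n), dv_good(n), dv_bad(n), dv_chosen(n), p_good(n);
  for (int t = 0; t < n; ++t) {
    double dg = decision_value(family, Q[0], V[0], p);
    double db = decision_value(family, Q[1], V[1], p);
    double z = p.beta * (dg - db);
    // log p computed through log1p(exp(.)) on the side that cannot overflow
    double lp_good = (z > 0) ? -std::log1p(std::exp(-z))
                             : z - std::log1p(std::exp(z));
    double lp_bad  = (z > 0) ? -z - std::log1p(std::exp(-z))
                             : -std::log1p(std::exp(z));
    int c = choice[t];
    ll[t] = (c == 1) ? lp_good : lp_bad;
    dv_good[t] = dg;
    dv_bad[t] = db;
    dv_chosen[t] = (c == 1) ? dg : db;
    p_good[t] = 1.0 / (1.0 + std::exp(-z));
    int a = (c == 1) ? 0 : 1, b = 1 - a;
    update_chosen(family, reward[t], Q[a], V[a], p);
    if (drift) Q[b] += p.alpha * (drift_target - Q[b]);
  }
  return List::create(_["loglik"] = ll, _["dv_good"] = dv_good,
                      _["dv_bad"] = dv_bad, _["dv_chosen"] = dv_chosen,
                      _["p_good"] = p_good);
}

// Simulate an agent on a trial-wise schedule of true arm parameters
// (points scale).  Uses R's RNG so set.seed() controls reproducibility.
// conf_const > 0 forces a constant confidence report (pathology injection).
// [[Rcpp::export]]
List bandit_simulate_cpp(NumericVector mu_good, NumericVector var_good,
                         NumericVector mu_bad, NumericVector var_bad,
                         int family, bool drift, NumericVector par,
                         double noise_sd, double q0, double v0,
                         double dv_lo, double dv_hi, int conf_const) {
  int n = mu_good.size();
  Par p(par);
  double Q[2] = {q0, q0}, V[2] = {v0, v0};
  double drift_target = drift ?
    ((family == 4) ? pow_utility(p.thresh, p.rho) : p.thresh) : 0.0;
  IntegerVector choice(n), confidence(n), reward(n);
  NumericVector dv_chosen(n), p_good(n);
  for (int t = 0; t < n; ++t) {
    double dg = decision_value(family, Q[0], V[0], p);
    double db = decision_value(family, Q[1], V[1], p);
    double z = p.beta * (dg - db);
    double pg = 1.0 / (1.0 + std::exp(-z));
    int c = (unif_rand() < pg) ? 1 : 0;
    double mu = (c == 1) ? mu_good[t] : mu_bad[t];
    double sd = std::sqrt((c == 1) ? var_good[t] : var_bad[t]);
    double pts = std::round(R::rnorm(mu, sd));
    if (pts < 1.0) pts = 1.0;
    if (pts > 100.0) pts = 100.0;
    double r = pts / 100.0;
    double dvc = (c == 1) ? dg : db;
    int conf;
    if (conf_const > 0) {
      conf = conf_const;
    } else {
      double raw = 1.0 + 5.0 * (dvc - dv_lo) / (dv_hi - dv_lo);
      if (noise_sd > 0) raw += R::rnorm(0.0, noise_sd);
      long cr = std::lround(raw);
      if (cr < 1) cr = 1;
      if (cr > 6) cr = 6;
      conf = (int)cr;
    }
    choice[t] = c;
    reward[t] = (int)pts;
    confidence[t] = conf;
    dv_chosen[t] = dvc;
    p_good[t] = pg;
    int a = (c == 1) ? 0 : 1, b = 1 - a;
    update_chosen(family, r, Q[a], V[a], p);
    if (drift) Q[b] += p.alpha * (drift_target - Q[b]);
  }
  return List::create(_["choice"] = choice, _["reward"] = reward,
                      _["confidence"] = confidence,
                      _["dv_chosen"] = dv_chosen, _["p_good"] = p_good);
}
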