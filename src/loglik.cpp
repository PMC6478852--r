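#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double gl_softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log P(choose option with strength s1 over s2) under a softmax with unit
// temperature on pre-scaled strengths
static inline double log_softmax2(double s1, double s2) {
  return -gl_softplus(s2 - s1);
}

// Sequential negative log-likelihood for the dual-learning-rate Q model.
// chosen/other are 0-based symbol indices (A=0..F=5); update flags mark
// feedback trials (values change, day-1 beta); day2 flags mark the 24-h
// choice phase (day-2 beta, no update). Rewards are coded -1/0/+1.
// [[Rcpp::export]]
double q_nll_cpp(IntegerVector chosen, IntegerVector other,
                 NumericVector reward, LogicalVector update,
                 LogicalVector day2, double alpha_pos, double alpha_neg,
                 double beta, double beta_day2) {
  std::vector<double> Q(6, 0.0);
  double nll = 0.0;
  int n = chosen.size();
  for (int t = 0; t < n; ++t) {
    int c = chosen[t], o = other[t];
    double b = day2[t] ? beta_day2 : beta;
    nll -= log_softmax2(b * Q[c], b * Q[o]);
    if (update[t]) {
      double delta = reward[t] - Q[c];
      Q[c] += (delta > 0 ? alpha_pos : alpha_neg) * delta;
    }
  }
  return nll;
}

// Sequential negative log-likelihood for the opponent actor (OpAL) model:
// critic V with rate alpha_c, Hebbian Go/NoGo actors G and N with rates
// alpha_g/alpha_n, choice by beta_g*G - beta_n*N (day-2 gains on the 24-h
// phase). G and N floored at 1e-6.
// [[Rcpp::export]]
double opal_nll_cpp(IntegerVector chosen, IntegerVector other,
                    NumericVector reward, LogicalVector update,
                    LogicalVector day2, double alpha_g, double alpha_n,
                    double alpha_c, double beta_g, double beta_n,
                    double beta_g_day2, double beta_n_day2) {
  std::vector<double> V(6, 0.0), G(6, 1.0), N(6, 1.0);
  const double floor = 1e-6;
  double nll = 0.0;
  int n = chosen.size();
  for (int t = 0; t < n; ++t) {
    int c = chosen[t], o = other[t];
    double bg = day2[t] ? beta_g_day2 : beta_g;
    double bn = day2[t] ? beta_n_day2 : beta_n;
    double sc = bg * G[c] - bn * N[c];
    double so = bg * G[o] - bn * N[o];
    nll -= log_softmax2(sc, so);
    if (update[t]) {
      double delta = reward[t] - V[c];
      V[c] += alpha_c * delta;
      G[c] += alpha_g * G[c] * delta;
      N[c] += alpha_n * N[c] * (-delta);
      if (G[c] < floor) G[c] = floor;
      if (N[c] < floor) N[c] = floor;
    }
  }
  return nll;
}

// Simulate feedback trials for a Q-learning agent on a fixed schedule.
// p_sal / val_sal give each symbol's salient-outcome probability and coded
// value. Uses R's RNG so set.seed() in R controls reproducibility.
// Returns chosen indices, realised rewards, salient flags and final Q.
// [[Rcpp::export]]
List q_sim_learn_cpp(IntegerVector left, IntegerVector right,
                     NumericVector p_sal, NumericVector val_sal,
                     double alpha_pos, double alpha_neg, double beta,
                     NumericVector q_init) {
  int n = left.size();
  std::vector<double> Q(q_init.begin(), q_init.end());
  IntegerVector chosen(n);
  NumericVector reward(n);
  LogicalVector salient(n);
  for (int t = 0; t < n; ++t) {
    int l = left[t], r = right[t];
    double p_left = 1.0 / (1.0 + std::exp(-beta * (Q[l] - Q[r])));
    int c = (R::runif(0.0, 1.0) < p_left) ? l : r;
    bool sal = R::runif(0.0, 1.0) < p_sal[c];
    double rew = sal ? val_sal[c] : 0.0;
    chosen[t] = c;
    reward[t] = rew;
    salient[t] = sal;
    double delta = rew - Q[c];
    Q[c] += (delta > 0 ? alpha_pos : alpha_neg) * delta;
  }
  return List::create(_["chosen"] = chosen, _["reward"] = reward,
                      _["salient"] = salient, _["Q"] = NumericVector(Q.begin(), Q.end()));
}

// Simulate feedback trials for an OpAL agent on a fixed schedule.
// [[Rcpp::export]]
List opal_sim_learn_cpp(IntegerVector left, IntegerVector right,
                        NumericVector p_sal, NumericVector val_sal,
                        double alpha_g, double alpha_n, double alpha_c,
                        double beta_g, double beta_n) {
  int n = left.size();
  std::vector<double> V(6, 0.0), G(6, 1.0), N(6, 1.0);
  const double floor = 1e-6;
  IntegerVector chosen(n);
  NumericVector reward(n);
  LogicalVector salient(n);
  for (int t = 0; t < n; ++t) {
    int l = left[t], r = right[t];
    double sl = beta_g * G[l] - beta_n * N[l];
    double sr = beta_g * G[r] - beta_n * N[r];
    double p_left = 1.0 / (1.0 + std::exp(-(sl - sr)));
    int c = (R::runif(0.0, 1.0) < p_left) ? l : r;
    bool sal = R::runif(0.0, 1.0) < p_sal[c];
    double rew = sal ? val_sal[c] : 0.0;
    chosen[t] = c;
    reward[t] = rew;
    salient[t] = sal;
    double delta = rew - V[c];
    V[c] += alpha_c * delta;
    G[c] += alpha_g * G[c] * delta;
    N[c] += alpha_n * N[c] * (-delta);
    if (G[c] < floor) G[c] = floor;
    if (N[c] < floor) N[c] = floor;
  }
  return List::create(_["chosen"] = chosen, _["reward"] = reward,
                      _["salient"] = salient,
                      _["V"] = NumericVector(V.begin(), V.end()),
                      _["G"] = NumericVector(G.begin(), G.end()),
                      _["N"] = NumericVector(N.begin(), N.end()));
}
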