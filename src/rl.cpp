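#include <Rcpp.h>
using namespace Rcpp;

// Fast paths for the Q-learning model.  Conventions shared with the R layer:
// choices are coded 0 = deck A, 1 = deck B; rewards are 0/1; Q starts at
// (0, 0); only the chosen deck's value is updated; the softmax is evaluated
// at the pre-choice Q-state.  All randomness goes through R's RNG so that
// set.seed() reproducibility holds across the R/C++ boundary.

static const double PROB_FLOOR = 1e-12;  // floor on per-trial choice prob

inline double prob_choose_a(double qa, double qb, double beta) {
  // logistic of beta * (qa - qb); stable because |qa - qb| <= 1
  return 1.0 / (1.0 + std::exp(-beta * (qa - qb)));
}

// Simulate one full session over a block schedule.
// [[Rcpp::export]]
List sim_session_cpp(NumericVector prob_a, NumericVector prob_b,
                     IntegerVector n_trials, double alpha, double beta) {
  const int n_blocks = prob_a.size();
  int total = 0;
  for (int b = 0; b < n_blocks; ++b) total += n_trials[b];
  IntegerVector block(total), choice(total), reward(total);
  double qa = 0.0, qb = 0.0;
  int t = 0;
  for (int b = 0; b < n_blocks; ++b) {
    for (int k = 0; k < n_trials[b]; ++k, ++t) {
      const double pa = prob_choose_a(qa, qb, beta);
      const int ch = (unif_rand() < pa) ? 0 : 1;
      const double pr = (ch == 0) ? prob_a[b] : prob_b[b];
      const int rw = (unif_rand() < pr) ? 1 : 0;
      if (ch == 0) qa += alpha * (rw - qa);
      else         qb += alpha * (rw - qb);
      block[t] = b + 1;
      choice[t] = ch;
      reward[t] = rw;
    }
  }
  return List::create(_["block"] = block, _["choice"] = choice,
                      _["reward"] = reward);
}

// Total scores of n_reps independent sessions (grid-study workhorse).
// [[Rcpp::export]]
NumericVector sim_scores_cpp(NumericVector prob_a, NumericVector prob_b,
                             IntegerVector n_trials, double alpha,
                             double beta, int n_reps) {
  const int n_blocks = prob_a.size();
  NumericVector scores(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    double qa = 0.0, qb = 0.0;
    int score = 0;
    for (int b = 0; b < n_blocks; ++b) {
      for (int k = 0; k < n_trials[b]; ++k) {
        const double pa = prob_choose_a(qa, qb, beta);
        const int ch = (unif_rand() < pa) ? 0 : 1;
        const double pr = (ch == 0) ? prob_a[b] : prob_b[b];
        const int rw = (unif_rand() < pr) ? 1 : 0;
        if (ch == 0) qa += alpha * (rw - qa);
        else         qb += alpha * (rw - qb);
        score += rw;
      }
    }
    scores[r] = score;
  }
  return scores;
}

// Log-likelihood of one recorded choice sequence under (alpha, beta).
// [[Rcpp::export]]
double loglik_cpp(IntegerVector choice, IntegerVector reward, double alpha,
                  double beta) {
  const int n = choice.size();
  double qa = 0.0, qb = 0.0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const double pa = prob_choose_a(qa, qb, beta);
    double p = (choice[t] == 0) ? pa : 1.0 - pa;
    if (p < PROB_FLOOR) p = PROB_FLOOR;
    ll += std::log(p);
    if (choice[t] == 0) qa += alpha * (reward[t] - qa);
    else                qb += alpha * (reward[t] - qb);
  }
  return ll;
}

// Vectorised log-likelihood over a cohort: one (alpha, beta) per subject.
// Used by the MCMC sampler so each iteration costs a single .Call.
// [[Rcpp::export]]
NumericVector loglik_all_cpp(List choices, List rewards, NumericVector alpha,
                             NumericVector beta) {
  const int n_sub = choices.size();
  NumericVector out(n_sub);
  for (int i = 0; i < n_sub; ++i) {
    IntegerVector ch = choices[i];
    IntegerVector rw = rewards[i];
    if (!R_finite(alpha[i]) || !R_finite(beta[i])) {
      out[i] = R_NegInf;
      continue;
    }
    out[i] = loglik_cpp(ch, rw, alpha[i], beta[i]);
  }
  return out;
}
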