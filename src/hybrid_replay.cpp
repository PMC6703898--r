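#include <Rcpp.h>
using namespace Rcpp;

// Replays the hybrid model-free/model-based learner over one session and
// accumulates the log-likelihood of the observed first-stage choices.
//
// Conventions (all 0-based):
//   start_state  in {0, 1}; action_local in {0, 1} within the start state
//   (global spaceship id = 2 * start_state + action_local)
//   planet       in {0 = red, 1 = purple}
//   key          in {0 = left, 1 = right}; left_action gives the local
//   action shown on the left key on that trial.
// miss1 trials contribute nothing and leave all learner state (including
// the previous-action / previous-key memory) untouched. miss2 trials
// contribute the first-stage choice term and the transition update, but no
// reward-driven update (no reward was delivered).
//
// Per-trial parameter vectors let a single routine serve every model
// variant: condition-dependent parameters are resolved to trial length in
// R before the call. eta is expected to be 1 on stable-block trials.

// [[Rcpp::export]]
List hybrid_replay_cpp(IntegerVector start_state,
                       IntegerVector action_local,
                       IntegerVector key1,
                       IntegerVector planet,
                       NumericVector reward,
                       IntegerVector miss1,
                       IntegerVector miss2,
                       IntegerVector left_action,
                       NumericVector alpha_t,
                       NumericVector lam_t,
                       NumericVector eta_t,
                       NumericVector etacf_t,
                       NumericVector beta_t,
                       NumericVector pi_t,
                       NumericVector rho_t,
                       NumericVector omega_t,
                       double q_init,
                       bool trace) {
  const int n = start_state.size();

  double q1[2][2];            // stage-1 model-free values [state][local action]
  double q2[2];               // planet values (stage-2 model-free = model-based)
  double t_red[2][2];         // P(planet red | state, local action)
  for (int s = 0; s < 2; ++s) {
    q2[s] = q_init;
    for (int a = 0; a < 2; ++a) {
      q1[s][a] = q_init;
      t_red[s][a] = 0.5;
    }
  }
  int prev_global = -1;       // last chosen spaceship (global id), -1 = none
  int prev_key = -1;          // last pressed first-stage key, -1 = none

  double loglik = 0.0;
  NumericVector ll_t, q2_pre;
  if (trace) {
    ll_t = NumericVector(n, NA_REAL);
    q2_pre = NumericVector(n, NA_REAL);
  }

  for (int t = 0; t < n; ++t) {
    if (miss1[t] == 1) continue;          // aborted trial: nothing shown, nothing learned

    const int s = start_state[t];
    const int ac = action_local[t];
    const double om = omega_t[t];

    // choice probabilities from pre-trial beliefs
    double v[2];
    for (int a = 0; a < 2; ++a) {
      const double qmb = t_red[s][a] * q2[0] + (1.0 - t_red[s][a]) * q2[1];
      const double qnet = (1.0 - om) * q1[s][a] + om * qmb;
      const int global = 2 * s + a;
      const double rep = (global == prev_global) ? 1.0 : 0.0;
      const int key_of_a = (a == left_action[t]) ? 0 : 1;
      const double resp = (prev_key >= 0 && key_of_a == prev_key) ? 1.0 : 0.0;
      v[a] = beta_t[t] * qnet + pi_t[t] * rep + rho_t[t] * resp;
    }
    const double m = (v[0] > v[1]) ? v[0] : v[1];
    const double lse = m + std::log(std::exp(v[0] - m) + std::exp(v[1] - m));
    const double ll = v[ac] - lse;
    loglik += ll;
    if (trace) ll_t[t] = ll;

    const int p = planet[t];

    // transition learning: factual update for the taken action, then
    // counterfactual update for the untaken action (anti-correlated task)
    const double eta = eta_t[t];
    const double etacf = etacf_t[t];
    t_red[s][ac] = (1.0 - eta) * t_red[s][ac] + eta * (p == 0 ? 1.0 : 0.0);
    const int ao = 1 - ac;                // untaken action leads to the other planet
    t_red[s][ao] = (1.0 - etacf) * t_red[s][ao] + etacf * (p == 1 ? 1.0 : 0.0);

    if (trace) q2_pre[t] = q2[p];

    // SARSA(lambda) reward update, only when a reward was delivered
    if (miss2[t] == 0) {
      const double r = reward[t];
      const double d1 = q2[p] - q1[s][ac];
      const double d2 = r - q2[p];
      q1[s][ac] += alpha_t[t] * d1 + alpha_t[t] * lam_t[t] * d2;
      q2[p] += alpha_t[t] * d2;
    }

    prev_global = 2 * s + ac;
    prev_key = key1[t];
  }

  NumericMatrix q1_out(2, 2), t_out(2, 2);
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < 2; ++a) {
      q1_out(s, a) = q1[s][a];
      t_out(s, a) = t_red[s][a];
    }

  List out = List::create(_["loglik"] = loglik,
                          _["q1"] = q1_out,
                          _["q2"] = NumericVector::create(q2[0], q2[1]),
                          _["t_red"] = t_out);
  if (trace) {
    out["ll_t"] = ll_t;
    out["q2_pre"] = q2_pre;
  }
  return out;
}
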