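#' Initial learner state
#'
#' Model-free values start at the arithmetic mean of the minimum and maximum
#' possible reward (4.5 under the default 0--9 bounds) for every state and
#' action, and all transition probabilities start at 0.5 (the agent begins
#' without knowledge of the current transition structure). No previous
#' action or response key is set.
#'
#' @param config A [task_config()].
#' @return An object of class `metarl_learner_state`: list with `q1`
#'   (`2 x 2` matrix of stage-1 values, rows = start states, cols = local
#'   actions), `q2` (length-2 planet values), `transition` (`2 x 2 x 2`
#'   array `T[s1, a1, s2]`), `prev_action` and `prev_key` (`NA` = none).
#' @export
init_learner_state <- function(config) {
  validate_task_config(config)
  q0 <- mean(config$reward_bounds)
  st <- list(q1 = matrix(q0, 2, 2),
             q2 = rep(q0, 2),
             transition = array(0.5, dim = c(2, 2, 2)),
             prev_action = NA_integer_,
             prev_key = NA_integer_)
  class(st) <- "metarl_learner_state"
  st
}

#' Model-based action values for a first-stage state
#'
#' `Q_MB(s1, a1) = sum_s2 T(s2 | s1, a1) * Q_MF(s2)`: second-stage values
#' weighted by the learned transition probabilities. At the second stage the
#' model-based and model-free values coincide (both estimate the immediate
#' reward), so planet values enter directly.
#'
#' @param state A `metarl_learner_state`.
#' @param s1 Start state (0 or 1).
#' @return Numeric length-2 vector of values for the two local actions.
#' @export
mb_values <- function(state, s1) {
  tr <- state$transition[s1 + 1L, , ]          # 2 x 2: action x planet
  as.numeric(tr %*% state$q2)
}

#' First-stage choice probabilities under the hybrid model
#'
#' Net values mix model-free and model-based values with the model-based
#' weight of the trial's condition cell,
#' `Q_net = (1 - omega) * Q_MF + omega * Q_MB`, and a softmax with choice
#' and response stickiness maps them to probabilities:
#' `P(a) proportional to exp(beta * Q_net(a) + pi * rep(a) + rho * resp(a))`,
#' where `rep(a) = 1` iff `a` is the spaceship chosen on the previous trial
#' and `resp(a) = 1` iff `a` sits on the key pressed on the previous trial.
#' The computation uses log-sum-exp normalization and is taken on the
#' pre-trial beliefs.
#'
#' @param state A `metarl_learner_state`.
#' @param s1 Start state (0 or 1).
#' @param params Parameter vector from [model_params()].
#' @param omega_cell Condition cell name, e.g. `"high_variable"`, selecting
#'   which model-based weight applies.
#' @param left_action Local action displayed on the left key this trial
#'   (0 or 1).
#' @return Numeric length-2 probability vector (sums to 1).
#' @export
choice_prob <- function(state, s1, params, omega_cell = "low_stable",
                        left_action = 0L) {
  omega <- unname(params[[paste0("omega_", omega_cell)]])
  qmf <- state$q1[s1 + 1L, ]
  qmb <- mb_values(state, s1)
  qnet <- (1 - omega) * qmf + omega * qmb
  global <- 2L * s1 + 0:1
  rep_a <- as.numeric(!is.na(state$prev_action) & global == state$prev_action)
  key_of <- as.integer(0:1 != left_action)     # 0 = left, 1 = right
  resp_a <- as.numeric(!is.na(state$prev_key) & key_of == state$prev_key)
  v <- unname(params[["beta"]]) * qnet +
    unname(params[["pi"]]) * rep_a + unname(params[["rho"]]) * resp_a
  m <- max(v)
  p <- exp(v - m)
  p / sum(p)
}

#' SARSA(lambda) model-free value update
#'
#' Computes the two reward prediction errors on the pre-update values,
#' `d1 = Q_MF(s2) - Q_MF(s1, a1)` and `d2 = r - Q_MF(s2)`, then applies
#' `Q_MF(s1, a1) += alpha * d1 + alpha * lam * d2` and
#' `Q_MF(s2) += alpha * d2`. Unvisited entries are unchanged.
#'
#' @param state A `metarl_learner_state`.
#' @param s1 Start state (0/1). @param action Local action taken (0/1).
#' @param planet Planet visited (0/1). @param reward Obtained reward
#'   (treasure units); must be present.
#' @param alpha Reward learning rate. @param lam Eligibility-trace decay.
#' @return The updated state.
#' @export
mf_update <- function(state, s1, action, planet, reward, alpha, lam) {
  if (is.na(reward)) stop("mf_update requires an observed reward", call. = FALSE)
  q1 <- state$q1[s1 + 1L, action + 1L]
  q2 <- state$q2[planet + 1L]
  d1 <- q2 - q1
  d2 <- reward - q2
  state$q1[s1 + 1L, action + 1L] <- q1 + alpha * d1 + alpha * lam * d2
  state$q2[planet + 1L] <- q2 + alpha * d2
  state
}

#' Transition-probability update with counterfactual learning
#'
#' For the taken action the state prediction error
#' `dSPE = 1 - T(s2 | s1, a1)` moves probability onto the observed planet:
#' `T(s2 | s1, a1) += eta * dSPE`, with the complementary entry scaled by
#' `(1 - eta)`. Because the two spaceships of a state always lead to
#' different planets, the untaken action's destination can be inferred; its
#' row receives the analogous counterfactual update with rate `eta_cf`
#' toward the other planet. Each row of `T` keeps summing to 1.
#'
#' @inheritParams mf_update
#' @param eta Transition learning rate for the experienced transition.
#' @param eta_cf Counterfactual transition learning rate.
#' @return The updated state.
#' @export
transition_update <- function(state, s1, action, planet, eta, eta_cf = eta) {
  tr <- state$transition
  obs <- as.numeric(0:1 == planet)             # one-hot observed planet
  tr[s1 + 1L, action + 1L, ] <- (1 - eta) * tr[s1 + 1L, action + 1L, ] + eta * obs
  cf <- 1 - obs                                # inferred destination of the other ship
  other <- 1L - action
  tr[s1 + 1L, other + 1L, ] <- (1 - eta_cf) * tr[s1 + 1L, other + 1L, ] + eta_cf * cf
  state$transition <- tr
  state
}

# Flatten a dataset's observations into the integer/double arrays the C++
# replay expects. Missing entries become -1 (integers) / NA (reward).
obs_arrays <- function(dataset) {
  obs <- dataset$obs
  tr <- dataset$sequence$trials
  stopifnot(nrow(obs) == nrow(tr))
  a_local <- obs$action1 - 2L * tr$start_state
  list(start_state = as.integer(tr$start_state),
       action_local = as.integer(ifelse(is.na(a_local), -1L, a_local)),
       key1 = as.integer(ifelse(is.na(obs$key1), -1L, obs$key1)),
       planet = as.integer(ifelse(is.na(obs$planet), -1L, obs$planet)),
       reward = as.numeric(obs$reward),
       miss1 = as.integer(obs$miss1),
       miss2 = as.integer(obs$miss2),
       left_action = as.integer(tr$left_action))
}

# Shared driver for sequence_loglik() / replay_learner().
replay_dataset <- function(dataset, params, variant, trace) {
  check_params_in_support(params, variant)
  arr <- obs_arrays(dataset)
  tp <- resolve_trial_params(params, variant, dataset$sequence$trials)
  q0 <- mean(dataset$sequence$config$reward_bounds)
  hybrid_replay_cpp(arr$start_state, arr$action_local, arr$key1, arr$planet,
                    arr$reward, arr$miss1, arr$miss2, arr$left_action,
                    tp$alpha, tp$lam, tp$eta, tp$eta_cf,
                    tp$beta, tp$pi, tp$rho, tp$omega,
                    q0, trace)
}

#' Log-likelihood of a behavioral dataset under the hybrid model
#'
#' Iterates the session in trial order, selecting the model-based weight by
#' each trial's stakes and transition-condition cell, and accumulates the
#' log-probability of every observed first-stage choice. The transition
#' learning rate is fixed at 1 on stable-block trials and takes its fitted
#' value in variable blocks. Trials with a missed first-stage response
#' contribute no likelihood term and trigger no updates; trials with a
#' missed second-stage response contribute the first-stage term and the
#' transition update (the planet was observed) but no reward update.
#'
#' @param dataset A `metarl_dataset` (see [simulate_agent()] or
#'   [read_choice_csv()]).
#' @param params Named parameter vector matching the variant's layout.
#' @param variant Model variant name (see [variant_layout()]).
#' @return Scalar log-likelihood (0 for a session with no valid first-stage
#'   responses).
#' @export
sequence_loglik <- function(dataset, params, variant = "standard") {
  res <- replay_dataset(dataset, params, variant, trace = FALSE)
  ll <- res$loglik
  if (!is.finite(ll)) stop("log-likelihood accumulation produced a non-finite value",
                           call. = FALSE)
  ll
}

#' Replay a fitted learner over a session
#'
#' Runs the same forward pass as [sequence_loglik()] but returns the
#' per-trial traces: the log-probability of each observed choice and the
#' pre-update model-free value of the visited planet (the trial-wise
#' second-stage reward expectation used as a regression covariate).
#'
#' @inheritParams sequence_loglik
#' @return List with `loglik`, `ll_t` (per-trial log-probabilities, `NA` on
#'   missed trials) and `q2_pre` (per-trial second-stage reward expectation,
#'   `NA` on first-stage misses).
#' @export
replay_learner <- function(dataset, params, variant = "standard") {
  res <- replay_dataset(dataset, params, variant, trace = TRUE)
  list(loglik = res$loglik, ll_t = res$ll_t, q2_pre = res$q2_pre)
}
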