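#' Generate drifting reward random walks for the two planets
#'
#' Each planet's reward follows an independent random walk: at every step a
#' Gaussian increment (mean 0, sd `reward_walk_sd`) is added, excursions past
#' a boundary are folded back symmetrically (`x -> 2 * bound - x`, iterated
#' until inside), and the value is rounded to an integer. Initial values are
#' drawn uniformly over the integer bounds.
#'
#' @param config A [task_config()].
#' @param n_trials Number of steps (trials) to generate.
#' @param seed Optional RNG seed.
#' @return Integer matrix `n_trials x 2` with columns `red` and `purple`.
#' @export
generate_reward_walks <- function(config, n_trials, seed = NULL) {
  validate_task_config(config)
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1)
    stop("n_trials must be a positive integer", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)
  lo <- config$reward_bounds[1]
  hi <- config$reward_bounds[2]
  walks <- matrix(0L, nrow = n_trials, ncol = 2,
                  dimnames = list(NULL, c("red", "purple")))
  for (p in 1:2) {
    v <- as.numeric(sample(lo:hi, 1L))
    walks[1, p] <- as.integer(round(v))
    if (n_trials > 1L) {
      eps <- stats::rnorm(n_trials - 1L, mean = 0, sd = config$reward_walk_sd)
      for (t in 2:n_trials) {
        v <- reflect_into(v + eps[t - 1L], lo, hi)
        v <- round(v)
        walks[t, p] <- as.integer(v)
      }
    }
  }
  walks
}

# Fold a value back into [lo, hi] by symmetric reflection at the bounds.
reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' Initial spaceship-to-planet transition structure
#'
#' Within each first-stage state the two spaceships lead to distinct planets
#' (anti-correlated structure). The assignment is drawn uniformly.
#'
#' @param seed Optional RNG seed.
#' @return Integer matrix `2 x 2`: `structure[s, a]` is the planet
#'   (0 = red, 1 = purple) reached from start state `s` (row `s + 1`) by
#'   local action `a` (column `a + 1`).
#' @export
random_transition_structure <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t(vapply(1:2, function(s) sample(0:1), integer(2)))
}

#' Swap the destination planets of one start state's spaceships
#'
#' @param structure A `2 x 2` transition structure
#'   (see [random_transition_structure()]).
#' @param state Start state whose action pair swaps destinations (0 or 1).
#' @return The reversed structure; the other state's row is untouched.
#' @export
apply_reversal <- function(structure, state) {
  if (!(length(state) == 1L && state %in% c(0, 1)))
    stop("state must be 0 or 1", call. = FALSE)
  structure[state + 1L, ] <- structure[state + 1L, 2:1]
  structure
}

#' Generate a full trial sequence for the task
#'
#' Produces the per-trial design: block and condition labels, start states,
#' stakes cues, key layout, reward walks, reversal schedule and the initial
#' transition structure. Within every block exactly half of the trials are
#' low-stakes, counterbalanced over the two start states; trial order is
#' randomized. Reversal gaps are drawn uniformly from
#' `config$reversal_interval`, the first gap counted from block start, and
#' each reversal affects a uniformly chosen start state. A reversal listed at
#' trial `t` is in effect from trial `t` onwards.
#'
#' @param config A [task_config()].
#' @param seed Optional RNG seed (falls back to `config$seed` if set).
#' @return An object of class `metarl_trial_sequence`: a list with elements
#'   `config`, `trials` (data frame), `reversals` (data frame with columns
#'   `trial`, `state`), `walks` (integer matrix) and `initial_transitions`.
#' @export
generate_trial_sequence <- function(config, seed = NULL) {
  validate_task_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  tpb <- config$trials_per_block
  if (tpb %% 4L != 0L)
    stop("trials_per_block must be divisible by 4 to counterbalance stakes ",
         "over start states", call. = FALSE)
  n <- n_trials(config)

  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    # exact counterbalancing: tpb/2 trials per start state, half of each low
    start_state <- c(rep(0L, tpb %/% 2L), rep(1L, tpb %/% 2L))
    stakes <- c(rep(c("low", "high"), each = tpb %/% 4L),
                rep(c("low", "high"), each = tpb %/% 4L))
    ord <- sample.int(tpb)
    blocks[[b]] <- data.frame(
      block = b - 1L,
      block_condition = config$block_order[b],
      start_state = start_state[ord],
      stakes = stakes[ord],
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, blocks)
  trials$trial <- seq_len(n) - 1L
  trials$left_action <- sample(0:1, n, replace = TRUE)
  trials <- trials[, c("trial", "block", "block_condition", "start_state",
                       "stakes", "left_action")]
  rownames(trials) <- NULL

  # reversal schedule: gaps uniform over the configured interval,
  # restarted at each variable block
  lo <- config$reversal_interval[1]
  hi <- config$reversal_interval[2]
  ev_trial <- integer(0)
  ev_state <- integer(0)
  for (b in seq_len(config$n_blocks)) {
    if (config$block_order[b] != "variable") next
    b0 <- (b - 1L) * tpb
    t_next <- b0 + sample(lo:hi, 1L)
    while (t_next < b0 + tpb) {
      ev_trial <- c(ev_trial, t_next)
      ev_state <- c(ev_state, sample(0:1, 1L))
      t_next <- t_next + sample(lo:hi, 1L)
    }
  }
  reversals <- data.frame(trial = ev_trial, state = ev_state)

  walks <- generate_reward_walks(config, n)
  structure0 <- random_transition_structure()

  seq_obj <- list(config = config,
                  trials = trials,
                  reversals = reversals,
                  walks = walks,
                  initial_transitions = structure0)
  class(seq_obj) <- "metarl_trial_sequence"
  seq_obj
}

#' Transition structure in effect at a given trial
#'
#' Applies, in order, every reversal of the sequence scheduled at or before
#' `trial` to the initial structure.
#'
#' @param sequence A `metarl_trial_sequence`.
#' @param trial 0-based trial index.
#' @return A `2 x 2` transition structure.
#' @export
transitions_at_trial <- function(sequence, trial) {
  st <- sequence$initial_transitions
  ev <- sequence$reversals
  if (nrow(ev)) {
    for (i in which(ev$trial <= trial)) st <- apply_reversal(st, ev$state[i])
  }
  st
}

#' Resolve one first-stage choice against the environment
#'
#' @param structure Transition structure in effect on this trial.
#' @param trial_row One row of `sequence$trials`.
#' @param action Local first-stage action (0 or 1) within the trial's start
#'   state.
#' @param walks Reward-walk matrix of the sequence.
#' @param config The task configuration.
#' @return List with `planet` (0 = red, 1 = purple), `reward` (treasure
#'   units) and `points` (reward times the trial's stakes multiplier).
#' @export
task_step <- function(structure, trial_row, action, walks, config) {
  if (!(length(action) == 1L && action %in% c(0, 1)))
    stop("action must be a local action index 0 or 1", call. = FALSE)
  planet <- structure[trial_row$start_state + 1L, action + 1L]
  reward <- walks[trial_row$trial + 1L, planet + 1L]
  mult <- unname(config$stakes_multipliers[[trial_row$stakes]])
  list(planet = as.integer(planet),
       reward = as.numeric(reward),
       points = as.numeric(reward) * mult)
}

#' Export a trial sequence as a long-format data frame
#'
#' One row per trial with the design columns, per-planet rewards and the
#' reversal markers (`reversal_event` 0/1, `affected_state` -1 if none).
#'
#' @param sequence A `metarl_trial_sequence`.
#' @return A data frame; write it with [utils::write.csv()] as needed.
#' @export
sequence_to_df <- function(sequence) {
  tr <- sequence$trials
  out <- data.frame(trial = tr$trial,
                    block = tr$block,
                    block_condition = tr$block_condition,
                    start_state = tr$start_state,
                    stakes = tr$stakes,
                    left_action = tr$left_action,
                    reward_red = sequence$walks[, 1],
                    reward_purple = sequence$walks[, 2],
                    reversal_event = 0L,
                    affected_state = -1L,
                    stringsAsFactors = FALSE)
  ev <- sequence$reversals
  if (nrow(ev)) {
    out$reversal_event[ev$trial + 1L] <- 1L
    out$affected_state[ev$trial + 1L] <- ev$state
  }
  out
}
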