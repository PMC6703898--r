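# Small task configurations and hand-buildable datasets used across tests.

tiny_config <- function(trials_per_block = 4L,
                        block_order = c("stable", "variable")) {
  task_config(n_blocks = length(block_order),
              trials_per_block = trials_per_block,
              block_order = block_order)
}

# A dataset with arbitrary (not model-generated) observations on a real
# trial sequence: random choices, consistent keys, random planets/rewards,
# and misses at the given rates. Exercises the likelihood on data the model
# did not generate.
random_dataset <- function(seed, n_per_block = 4L,
                           block_order = c("stable", "variable"),
                           miss_rate = 0.1) {
  set.seed(seed)
  cfg <- tiny_config(n_per_block, block_order)
  sq <- generate_trial_sequence(cfg, seed = seed + 1000L)
  n <- nrow(sq$trials)
  miss1 <- stats::rbinom(n, 1, miss_rate)
  miss2 <- ifelse(miss1 == 1, 0L, stats::rbinom(n, 1, miss_rate))
  a_local <- sample(0:1, n, replace = TRUE)
  gid <- ifelse(miss1 == 1, NA_integer_, 2L * sq$trials$start_state + a_local)
  key1 <- ifelse(miss1 == 1, NA_integer_,
                 as.integer(a_local != sq$trials$left_action))
  planet <- ifelse(miss1 == 1, NA_integer_, sample(0:1, n, replace = TRUE))
  reward <- ifelse(miss1 == 1 | miss2 == 1, NA_real_,
                   sample(0:9, n, replace = TRUE))
  obs <- data.frame(trial = sq$trials$trial, block = sq$trials$block,
                    block_condition = sq$trials$block_condition,
                    stakes = sq$trials$stakes,
                    start_state = sq$trials$start_state,
                    action1 = gid, key1 = key1, planet = planet,
                    reward = reward, points = reward,
                    rt1_ms = NA_real_, rt2_ms = NA_real_,
                    miss1 = miss1, miss2 = miss2,
                    stringsAsFactors = FALSE)
  metarl:::make_dataset("oracle_case", "synthetic", sq, obs)
}

random_params <- function(seed, dual = FALSE) {
  set.seed(seed)
  model_params(alpha = runif(1), lam = runif(1), eta = runif(1),
               omega = runif(4), beta = runif(1, 0, 3),
               pi = rnorm(1, 0, 0.5), rho = rnorm(1, 0, 0.5),
               eta_cf = if (dual) runif(1) else NULL)
}
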