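test_that("baseline correction subtracts the mean available reward", {
  ds <- random_dataset(seed = 10, miss_rate = 0)
  # hand-set one trial: reward 7, planets at (6, 2) -> 7 - 4 = 3
  ds$sequence$walks[1, ] <- c(6L, 2L)
  ds$obs$reward[1] <- 7
  bc <- baseline_corrected_reward(ds)
  expect_equal(bc$per_trial[1], 3)

  ds$obs$miss1[2] <- 1L
  ds$obs$reward[2] <- NA_real_
  bc2 <- baseline_corrected_reward(ds)
  expect_true(is.na(bc2$per_trial[2]))
  expect_equal(bc2$mean, mean(bc2$per_trial, na.rm = TRUE))
})

test_that("a uniformly random chooser earns about zero corrected reward", {
  sq <- generate_trial_sequence(task_config(), seed = 30)
  means <- vapply(1:20, function(i) {
    ds <- simulate_agent(model_params(beta = 0, pi = 0, rho = 0), sq,
                         seed = 1000 + i)
    baseline_corrected_reward(ds)$mean
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("an always-better-planet chooser earns half the absolute walk gap", {
  cfg <- task_config()
  sq <- generate_trial_sequence(cfg, seed = 31)
  n <- nrow(sq$trials)
  better <- ifelse(sq$walks[, 1] >= sq$walks[, 2], 0L, 1L)
  obs <- data.frame(trial = sq$trials$trial, block = sq$trials$block,
                    block_condition = sq$trials$block_condition,
                    stakes = sq$trials$stakes,
                    start_state = sq$trials$start_state,
                    action1 = 2L * sq$trials$start_state, key1 = 0L,
                    planet = better,
                    reward = as.numeric(sq$walks[cbind(seq_len(n), better + 1L)]),
                    points = NA_real_, rt1_ms = NA_real_, rt2_ms = NA_real_,
                    miss1 = 0L, miss2 = 0L, stringsAsFactors = FALSE)
  ds <- metarl:::make_dataset("ideal", "synthetic", sq, obs)
  expect_equal(baseline_corrected_reward(ds)$mean,
               mean(abs(sq$walks[, 1] - sq$walks[, 2]) / 2))
})

test_that("revaluation flags mark the first valid visit after each reversal", {
  cfg <- tiny_config(trials_per_block = 20, block_order = "variable")
  sq <- generate_trial_sequence(cfg, seed = 1)
  # construct a deterministic schedule: reversal at trial 10 affecting state 0
  sq$reversals <- data.frame(trial = 10L, state = 0L)
  sq$trials$start_state <- rep(c(1L, 0L), 10)   # state 0 on odd trials
  obs <- data.frame(trial = sq$trials$trial, block = sq$trials$block,
                    block_condition = sq$trials$block_condition,
                    stakes = sq$trials$stakes,
                    start_state = sq$trials$start_state,
                    action1 = 2L * sq$trials$start_state, key1 = 0L,
                    planet = 0L, reward = 1, points = 1,
                    rt1_ms = 500, rt2_ms = 500, miss1 = 0L, miss2 = 0L,
                    stringsAsFactors = FALSE)
  ds <- metarl:::make_dataset("p", "younger", sq, obs)
  # trial 10 is state 1; trial 11 is the first state-0 trial at/after 10
  expect_equal(which(identify_revaluation_trials(ds)) - 1L, 11L)

  # a missed response postpones the observation to the next state-0 visit
  ds$obs$miss1[12] <- 1L
  expect_equal(which(identify_revaluation_trials(ds)) - 1L, 13L)

  # two pending reversals on the same unvisited state collapse to one flag
  ds$obs$miss1[12] <- 0L
  ds$sequence$reversals <- data.frame(trial = c(10L, 10L), state = c(0L, 0L))
  expect_equal(which(identify_revaluation_trials(ds)) - 1L, 11L)

  # no reversals (stable block): no flags
  ds$sequence$reversals <- data.frame(trial = integer(0), state = integer(0))
  expect_equal(sum(identify_revaluation_trials(ds)), 0)
})

test_that("revaluation flags occur only in variable blocks, at most one per event", {
  spec <- cohort_spec(n_per_group = 3, seed = 3)
  co <- simulate_cohort(spec, task_config())
  for (ds in co$datasets) {
    fl <- identify_revaluation_trials(ds)
    expect_true(all(ds$obs$block_condition[fl] == "variable"))
    expect_lte(sum(fl), nrow(ds$sequence$reversals))
  }
})

test_that("mutual nearest-neighbour matching equals brute force on toy input", {
  a <- data.frame(participant = c("a1", "a2"), mean_bc_reward = c(1.0, 2.0))
  b <- data.frame(participant = c("b1", "b2"), mean_bc_reward = c(1.1, 5.0))
  m <- performance_match(a, b)
  expect_equal(m$pairs$participant_a, "a1")
  expect_equal(m$pairs$participant_b, "b1")
  expect_equal(m$unmatched_a, "a2")      # a2's nearest is b1, not mutual
  expect_equal(m$unmatched_b, "b2")

  # symmetric in group order
  m2 <- performance_match(b, a)
  expect_equal(m2$pairs$participant_b, m$pairs$participant_a)
  expect_equal(m2$pairs$participant_a, m$pairs$participant_b)

  # identical groups: everyone pairs with their duplicate
  m3 <- performance_match(a, a)
  expect_equal(nrow(m3$pairs), 2)
  expect_equal(m3$pairs$diff, c(0, 0))

  # singletons are forced into one pair
  m4 <- performance_match(a[1, ], b[2, ])
  expect_equal(nrow(m4$pairs), 1)

  # distance ties break toward the earlier entry, deterministically
  a5 <- data.frame(participant = "x", mean_bc_reward = 0)
  b5 <- data.frame(participant = c("y1", "y2"), mean_bc_reward = c(-1, 1))
  m5 <- performance_match(a5, b5)
  expect_equal(m5$pairs$participant_b, "y1")
})

test_that("matching never reuses a participant across many random inputs", {
  for (s in 1:20) {
    set.seed(s)
    a <- data.frame(participant = paste0("a", 1:7),
                    mean_bc_reward = rnorm(7))
    b <- data.frame(participant = paste0("b", 1:5),
                    mean_bc_reward = rnorm(5))
    m <- performance_match(a, b)
    expect_equal(anyDuplicated(m$pairs$participant_a), 0)
    expect_equal(anyDuplicated(m$pairs$participant_b), 0)
    m_sw <- performance_match(b, a)
    expect_setequal(paste(m$pairs$participant_a, m$pairs$participant_b),
                    paste(m_sw$pairs$participant_b, m_sw$pairs$participant_a))
  }
})

test_that("RT preprocessing applies the 200 ms and block filters", {
  spec <- cohort_spec(n_per_group = 1, seed = 6)
  co <- simulate_cohort(spec, task_config())
  ds <- co$datasets[[1]]
  ds$obs$rt2_ms[ds$obs$block_condition == "variable"][1:3] <- c(199, 200, 250)
  tab <- rt_preprocess(ds)
  expect_false(199 %in% tab$rt2_ms)     # below 200 ms: dropped
  expect_true(200 %in% tab$rt2_ms)      # exactly 200 ms: kept
  expect_true(all(tab$rt2_ms >= 200))
  # only variable-block trials survive
  expect_true(all(ds$obs$block_condition[match(tab$trial, ds$obs$trial)] ==
                    "variable"))
  expect_equal(tab$log_rt2, log(tab$rt2_ms))
  expect_true(all(tab$revaluation %in% 0:1))
  expect_equal(unique(tab$old), as.integer(ds$group == "older"))
})

test_that("the expectation covariate replays the learner exactly", {
  sq <- generate_trial_sequence(task_config(), seed = 90)
  p <- model_params(alpha = .6, lam = .4, eta = .8, omega = c(.2, .7, .3, .6),
                    beta = 1.4, pi = .1, rho = .05)
  ds <- simulate_agent(p, sq, seed = 91)
  cov <- expectation_covariate(ds, p)
  expect_equal(cov[1], 4.5)             # first trial: initialization value
  expect_equal(cov, ds$sim_trace, tolerance = 1e-12)

  # alpha = 1: the covariate equals the last reward observed on that planet
  p1 <- model_params(alpha = 1, lam = 0, eta = 1, omega = .5, beta = 1)
  ds1 <- simulate_agent(p1, sq, seed = 92)
  cov1 <- expectation_covariate(ds1, p1)
  for (t in 2:320) {
    prev <- which(ds1$obs$planet[1:(t - 1)] == ds1$obs$planet[t] &
                    ds1$obs$miss1[1:(t - 1)] == 0 &
                    ds1$obs$miss2[1:(t - 1)] == 0)
    if (length(prev) && ds1$obs$miss1[t] == 0) {
      expect_equal(cov1[t], ds1$obs$reward[max(prev)])
    }
  }
})
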