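test_that("initial beliefs sit at the reward midpoint with flat transitions", {
  st <- init_learner_state(task_config())
  expect_true(all(st$q1 == 4.5))
  expect_true(all(st$q2 == 4.5))
  expect_true(all(st$transition == 0.5))
  expect_true(is.na(st$prev_action) && is.na(st$prev_key))

  st0 <- init_learner_state(task_config(reward_bounds = c(0L, 1L)))
  expect_true(all(st0$q1 == 0.5))
})

test_that("model-based values are transition-weighted planet values", {
  st <- init_learner_state(task_config())
  st$q2 <- c(8, 2)
  st$transition[1, 1, ] <- c(1, 0)
  st$transition[1, 2, ] <- c(0.5, 0.5)
  v <- mb_values(st, 0)
  expect_equal(v[1], 8)                       # deterministic transition
  expect_equal(v[2], 5)                       # 0.5*8 + 0.5*2
  # equal planet values: model-based values equal regardless of T
  st$q2 <- c(3, 3)
  st$transition[1, 1, ] <- c(0.9, 0.1)
  expect_equal(mb_values(st, 0), c(3, 3))
})

test_that("choice probabilities follow the stickiness-augmented softmax", {
  st <- init_learner_state(task_config())
  p0 <- choice_prob(st, 0, model_params(beta = 0, pi = 0, rho = 0))
  expect_equal(p0, c(0.5, 0.5))
  expect_equal(sum(p0), 1)

  # closed form: previous action a0, beta 0, pi 1 -> e/(e+1)
  st$prev_action <- 0L
  p1 <- choice_prob(st, 0, model_params(beta = 0, pi = 1, rho = 0))
  expect_equal(p1[1], exp(1) / (exp(1) + 1), tolerance = 1e-12)

  # pure model-based with symmetric planet beliefs ignores stage-1 values
  st2 <- init_learner_state(task_config())
  st2$q1[1, ] <- c(9, 0)
  p2 <- choice_prob(st2, 0, model_params(omega = 1, beta = 5))
  expect_equal(p2, c(0.5, 0.5))

  # response stickiness keys off the trial layout
  st3 <- init_learner_state(task_config())
  st3$prev_key <- 0L
  p3 <- choice_prob(st3, 0, model_params(beta = 0, rho = 1), left_action = 1L)
  expect_equal(p3[2], exp(1) / (exp(1) + 1))  # action 1 is on the left key
})

test_that("SARSA(lambda) update reproduces hand arithmetic and convexity", {
  cfg <- task_config()
  st <- init_learner_state(cfg)
  st$q2[1] <- 6
  up <- mf_update(st, 0, 0, 0, reward = 9, alpha = 0.5, lam = 1)
  expect_equal(up$q1[1, 1], 6.75)             # 4.5 + 0.5*1.5 + 0.5*1*3
  expect_equal(up$q2[1], 7.5)
  expect_equal(up$q1[1, 2], 4.5)              # unvisited entries unchanged
  expect_equal(up$q1[2, ], c(4.5, 4.5))

  same <- mf_update(st, 0, 0, 0, reward = 9, alpha = 0, lam = 0.7)
  expect_equal(same$q1, st$q1)
  expect_equal(same$q2, st$q2)
  expect_error(mf_update(st, 0, 0, 0, reward = NA, alpha = .5, lam = .5),
               "reward")

  # boundedness: random updates never leave the reward range
  set.seed(42)
  st <- init_learner_state(cfg)
  for (i in 1:500) {
    s <- sample(0:1, 1); a <- sample(0:1, 1); p <- sample(0:1, 1)
    st <- mf_update(st, s, a, p, sample(0:9, 1), runif(1), runif(1))
    expect_true(all(st$q1 >= 0 & st$q1 <= 9))
    expect_true(all(st$q2 >= 0 & st$q2 <= 9))
  }
})

test_that("transition updates conserve row sums and hit one-shot limits", {
  cfg <- task_config()
  st <- init_learner_state(cfg)
  # unit rates: observing a0 -> red makes both rows deterministic
  up <- transition_update(st, 0, 0, 0, eta = 1, eta_cf = 1)
  expect_equal(up$transition[1, 1, ], c(1, 0))
  expect_equal(up$transition[1, 2, ], c(0, 1))
  expect_equal(up$transition[2, , ], st$transition[2, , ])

  same <- transition_update(st, 0, 0, 0, eta = 0, eta_cf = 0)
  expect_equal(same$transition, st$transition)

  set.seed(7)
  for (i in 1:300) {
    st <- transition_update(st, sample(0:1, 1), sample(0:1, 1),
                            sample(0:1, 1), runif(1), runif(1))
    sums <- apply(st$transition, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(st$transition >= 0 & st$transition <= 1))
  }
})

test_that("uniform-policy likelihood is n * log(0.5) and misses drop out", {
  ds <- random_dataset(seed = 1, n_per_block = 8, miss_rate = 0.2)
  p <- model_params(beta = 0, pi = 0, rho = 0)
  n_valid <- sum(ds$obs$miss1 == 0)
  expect_equal(sequence_loglik(ds, p), n_valid * log(0.5), tolerance = 1e-12)

  ds$obs$miss1[] <- 1L
  ds$obs$action1[] <- NA_integer_
  ds$obs$key1[] <- NA_integer_
  ds$obs$planet[] <- NA_integer_
  ds$obs$reward[] <- NA_real_
  expect_equal(sequence_loglik(ds, model_params(beta = 2, pi = 1)), 0)
})

test_that("likelihood matches the brute-force oracle on random short datasets", {
  for (k in 1:100) {
    ds <- random_dataset(seed = k, n_per_block = 4, miss_rate = 0.15)
    p <- random_params(seed = 10000 + k)
    expect_equal(sequence_loglik(ds, p), oracle_loglik(ds, p),
                 tolerance = 1e-10)
  }
})

test_that("dual-rate likelihood matches the oracle with separate eta_cf", {
  for (k in 1:25) {
    ds <- random_dataset(seed = 300 + k, n_per_block = 4, miss_rate = 0.1)
    p <- random_params(seed = 20000 + k, dual = TRUE)
    expect_equal(sequence_loglik(ds, p, variant = "dual_transition_rate"),
                 oracle_loglik(ds, p, variant = "dual_transition_rate"),
                 tolerance = 1e-10)
  }
})

test_that("omega = 0 and omega = 1 reduce to pure-MF / pure-MB learners", {
  for (k in 1:30) {
    ds <- random_dataset(seed = 600 + k, n_per_block = 4, miss_rate = 0.1)
    base <- random_params(seed = 30000 + k)
    p_mf <- base; p_mf[paste0("omega_", c("low_stable", "high_stable",
                                          "low_variable", "high_variable"))] <- 0
    expect_equal(sequence_loglik(ds, p_mf), oracle_loglik_mf(ds, p_mf),
                 tolerance = 1e-10)
    p_mb <- base; p_mb[paste0("omega_", c("low_stable", "high_stable",
                                          "low_variable", "high_variable"))] <- 1
    expect_equal(sequence_loglik(ds, p_mb), oracle_loglik_mb(ds, p_mb),
                 tolerance = 1e-10)
  }
})

test_that("likelihood rejects out-of-bounds parameters", {
  ds <- random_dataset(seed = 5)
  p <- model_params(alpha = 1.2)
  expect_error(sequence_loglik(ds, p), "bounds")
  p2 <- model_params(beta = -1)
  expect_error(sequence_loglik(ds, p2), "bounds")
})

test_that("choice stickiness monotonically favors repeating the last action", {
  st <- init_learner_state(task_config())
  st$prev_action <- 2L          # previous choice: state 1, local action 0
  for (beta in c(0, 1, 5)) {
    probs <- vapply(seq(-1, 2, by = 0.25), function(pi_val) {
      choice_prob(st, 1, model_params(beta = beta, pi = pi_val))[1]
    }, numeric(1))
    expect_true(all(diff(probs) > 0))
  }
  # when the start state differs from the previous trial, rep is 0 for both
  p <- choice_prob(st, 0, model_params(beta = 0, pi = 3))
  expect_equal(p, c(0.5, 0.5))
})
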