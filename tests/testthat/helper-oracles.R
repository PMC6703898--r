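# Independent straight-line oracles for the hybrid-model likelihood.
# Deliberately coded from first principles, structured differently from the
# package implementation: state is rebuilt from scratch for every trial
# (O(n^2)), values are stored per global spaceship id, and the transition
# matrix is a full 2 x 2 x 2 array.

# Replay trials 1..upto of a dataset and return the learner state.
oracle_state_after <- function(dataset, params, upto, variant = "standard") {
  tr <- dataset$sequence$trials
  obs <- dataset$obs
  q0 <- mean(dataset$sequence$config$reward_bounds)
  q1 <- rep(q0, 4)                       # per global spaceship id 0..3
  q2 <- rep(q0, 2)                       # per planet
  Tm <- array(0.5, c(2, 2, 2))           # T[s1+1, a+1, planet+1]
  prev_gid <- NA
  prev_key <- NA
  alpha <- params[["alpha"]]; lam <- params[["lam"]]
  t_ix <- seq_len(upto)
  for (t in t_ix) {
    if (obs$miss1[t] == 1) next
    s <- tr$start_state[t]
    gid <- obs$action1[t]
    a <- gid - 2 * s
    p <- obs$planet[t]
    in_var <- tr$block_condition[t] == "variable"
    eta <- if (in_var) params[["eta"]] else 1
    eta_cf <- if (in_var && variant == "dual_transition_rate")
      params[["eta_cf"]] else eta
    # factual transition update
    dspe <- 1 - Tm[s + 1, a + 1, p + 1]
    Tm[s + 1, a + 1, p + 1] <- Tm[s + 1, a + 1, p + 1] + eta * dspe
    Tm[s + 1, a + 1, (1 - p) + 1] <- Tm[s + 1, a + 1, (1 - p) + 1] * (1 - eta)
    # counterfactual: the other spaceship leads to the other planet
    ao <- 1 - a
    dcf <- 1 - Tm[s + 1, ao + 1, (1 - p) + 1]
    Tm[s + 1, ao + 1, (1 - p) + 1] <- Tm[s + 1, ao + 1, (1 - p) + 1] + eta_cf * dcf
    Tm[s + 1, ao + 1, p + 1] <- Tm[s + 1, ao + 1, p + 1] * (1 - eta_cf)
    if (obs$miss2[t] == 0) {
      r <- obs$reward[t]
      d1 <- q2[p + 1] - q1[gid + 1]
      d2 <- r - q2[p + 1]
      q1[gid + 1] <- q1[gid + 1] + alpha * d1 + alpha * lam * d2
      q2[p + 1] <- q2[p + 1] + alpha * d2
    }
    prev_gid <- gid
    prev_key <- obs$key1[t]
  }
  list(q1 = q1, q2 = q2, Tm = Tm, prev_gid = prev_gid, prev_key = prev_key)
}

# Choice probability of the observed action on trial t, computed on the
# state rebuilt from all earlier trials.
oracle_trial_prob <- function(dataset, params, t, variant = "standard") {
  st <- oracle_state_after(dataset, params, t - 1, variant)
  tr <- dataset$sequence$trials
  obs <- dataset$obs
  s <- tr$start_state[t]
  cell <- paste(tr$stakes[t], tr$block_condition[t], sep = "_")
  omega <- params[[paste0("omega_", cell)]]
  num <- numeric(2)
  for (a in 0:1) {
    gid <- 2 * s + a
    qmb <- sum(st$Tm[s + 1, a + 1, ] * st$q2)
    qnet <- (1 - omega) * st$q1[gid + 1] + omega * qmb
    rep_a <- if (!is.na(st$prev_gid) && gid == st$prev_gid) 1 else 0
    key_a <- if (a == tr$left_action[t]) 0 else 1
    resp_a <- if (!is.na(st$prev_key) && key_a == st$prev_key) 1 else 0
    num[a + 1] <- exp(params[["beta"]] * qnet + params[["pi"]] * rep_a +
                        params[["rho"]] * resp_a)
  }
  chosen <- obs$action1[t] - 2 * s
  num[chosen + 1] / sum(num)
}

oracle_loglik <- function(dataset, params, variant = "standard") {
  obs <- dataset$obs
  ll <- 0
  for (t in seq_len(nrow(obs))) {
    if (obs$miss1[t] == 1) next
    ll <- ll + log(oracle_trial_prob(dataset, params, t, variant))
  }
  ll
}

# Pure model-free oracle: never consults the transition structure.
oracle_loglik_mf <- function(dataset, params) {
  tr <- dataset$sequence$trials
  obs <- dataset$obs
  q0 <- mean(dataset$sequence$config$reward_bounds)
  q1 <- rep(q0, 4)
  q2 <- rep(q0, 2)
  prev_gid <- NA
  prev_key <- NA
  ll <- 0
  for (t in seq_len(nrow(obs))) {
    if (obs$miss1[t] == 1) next
    s <- tr$start_state[t]
    gid <- obs$action1[t]
    v <- numeric(2)
    for (a in 0:1) {
      g <- 2 * s + a
      rep_a <- if (!is.na(prev_gid) && g == prev_gid) 1 else 0
      key_a <- if (a == tr$left_action[t]) 0 else 1
      resp_a <- if (!is.na(prev_key) && key_a == prev_key) 1 else 0
      v[a + 1] <- params[["beta"]] * q1[g + 1] + params[["pi"]] * rep_a +
        params[["rho"]] * resp_a
    }
    pr <- exp(v) / sum(exp(v))
    ll <- ll + log(pr[gid - 2 * s + 1])
    if (obs$miss2[t] == 0) {
      p <- obs$planet[t]
      d1 <- q2[p + 1] - q1[gid + 1]
      d2 <- obs$reward[t] - q2[p + 1]
      q1[gid + 1] <- q1[gid + 1] + params[["alpha"]] * d1 +
        params[["alpha"]] * params[["lam"]] * d2
      q2[p + 1] <- q2[p + 1] + params[["alpha"]] * d2
    }
    prev_gid <- gid
    prev_key <- obs$key1[t]
  }
  ll
}

# Pure model-based oracle: values come only from the transition model and
# planet-level reward expectations.
oracle_loglik_mb <- function(dataset, params) {
  tr <- dataset$sequence$trials
  obs <- dataset$obs
  q0 <- mean(dataset$sequence$config$reward_bounds)
  q2 <- rep(q0, 2)
  Tm <- array(0.5, c(2, 2, 2))
  prev_gid <- NA
  prev_key <- NA
  ll <- 0
  for (t in seq_len(nrow(obs))) {
    if (obs$miss1[t] == 1) next
    s <- tr$start_state[t]
    gid <- obs$action1[t]
    a1 <- gid - 2 * s
    v <- numeric(2)
    for (a in 0:1) {
      g <- 2 * s + a
      qmb <- sum(Tm[s + 1, a + 1, ] * q2)
      rep_a <- if (!is.na(prev_gid) && g == prev_gid) 1 else 0
      key_a <- if (a == tr$left_action[t]) 0 else 1
      resp_a <- if (!is.na(prev_key) && key_a == prev_key) 1 else 0
      v[a + 1] <- params[["beta"]] * qmb + params[["pi"]] * rep_a +
        params[["rho"]] * resp_a
    }
    pr <- exp(v) / sum(exp(v))
    ll <- ll + log(pr[a1 + 1])
    p <- obs$planet[t]
    in_var <- tr$block_condition[t] == "variable"
    eta <- if (in_var) params[["eta"]] else 1
    dspe <- 1 - Tm[s + 1, a1 + 1, p + 1]
    Tm[s + 1, a1 + 1, p + 1] <- Tm[s + 1, a1 + 1, p + 1] + eta * dspe
    Tm[s + 1, a1 + 1, (1 - p) + 1] <- Tm[s + 1, a1 + 1, (1 - p) + 1] * (1 - eta)
    ao <- 1 - a1
    dcf <- 1 - Tm[s + 1, ao + 1, (1 - p) + 1]
    Tm[s + 1, ao + 1, (1 - p) + 1] <- Tm[s + 1, ao + 1, (1 - p) + 1] + eta * dcf
    Tm[s + 1, ao + 1, p + 1] <- Tm[s + 1, ao + 1, p + 1] * (1 - eta)
    if (obs$miss2[t] == 0) {
      q2[p + 1] <- q2[p + 1] + params[["alpha"]] * (obs$reward[t] - q2[p + 1])
    }
    prev_gid <- gid
    prev_key <- obs$key1[t]
  }
  ll
}
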