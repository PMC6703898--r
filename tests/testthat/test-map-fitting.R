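test_that("prior densities match closed forms and reject out-of-support points", {
  pr <- prior_spec()
  p <- model_params(alpha = 0.5, lam = 0.5, eta = 0.5, omega = 0.5,
                    beta = 0.4, pi = 0, rho = 0)
  # Beta(2,2) at 0.5 has density 1.5
  expect_equal(log_prior(model_params(alpha = 0.5), "standard", pr) -
                 log_prior(model_params(alpha = 0.5), "standard", pr), 0)
  lp <- log_prior(p, "standard", pr)
  manual <- 7 * dbeta(0.5, 2, 2, log = TRUE) +
    dgamma(0.4, shape = 3, scale = 0.2, log = TRUE) +
    2 * dnorm(0, 0, 1, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12)
  expect_equal(dnorm(0, log = TRUE), -0.5 * log(2 * base::pi))

  expect_identical(log_prior(model_params(alpha = 1.2), "standard", pr), -Inf)
  expect_identical(log_prior(model_params(beta = -0.1), "standard", pr), -Inf)
})

test_that("each prior density integrates to one over its support", {
  pr <- prior_spec()
  f <- metarl:::prior_density_funs(pr)
  expect_equal(stats::integrate(function(x) exp(f$unit$logd(x)), 0, 1)$value,
               1, tolerance = 1e-6)
  expect_equal(stats::integrate(function(x) exp(f$positive$logd(x)), 0, Inf)$value,
               1, tolerance = 1e-6)
  expect_equal(stats::integrate(function(x) exp(f$real$logd(x)), -Inf, Inf)$value,
               1, tolerance = 1e-6)
})

test_that("the rate parameterization of the temperature prior is available", {
  pr_rate <- prior_spec(gamma_parameterization = "rate")
  f <- metarl:::prior_density_funs(pr_rate)
  expect_equal(f$positive$logd(2),
               dgamma(2, shape = 3, rate = 0.2, log = TRUE))
})

test_that("free-parameter counts match the model layouts", {
  expect_equal(count_free_params("standard"), 10L)
  expect_equal(count_free_params("exhaustive"), 26L)
  expect_equal(count_free_params("dual_transition_rate"), 11L)
  expect_error(variant_layout("bogus"))
})

test_that("AIC applies the 2k penalty to the MAP-point likelihood", {
  fake <- structure(list(variant = "standard", log_likelihood = -200),
                    class = "metarl_fit")
  expect_equal(aic(fake), 2 * 10 - 2 * (-200))
  fake$variant <- "dual_transition_rate"
  expect_equal(aic(fake), 2 * 11 + 400)
})

test_that("MAP of a single free parameter matches a dense grid search", {
  ds <- random_dataset(seed = 2, n_per_block = 4, miss_rate = 0)
  held <- model_params(alpha = .5, lam = .5, eta = .5, omega = .5,
                       beta = 1, pi = 0, rho = 0)
  held <- held[names(held) != "pi"]
  fit <- fit_map(ds, n_restarts = 5, seed = 3, fixed = held)
  # independent oracle: dense grid over pi on the same posterior definition
  objective <- function(pi_val) {
    p <- c(held, pi = pi_val)
    sequence_loglik(ds, p) + log_prior(p, "standard", prior_spec())
  }
  grid <- seq(-3, 3, by = 1e-3)
  pi_grid <- grid[which.max(vapply(grid, objective, numeric(1)))]
  expect_equal(unname(fit$params_hat[["pi"]]), pi_grid, tolerance = 1e-3)
  expect_equal(unname(fit$params_hat[["alpha"]]), 0.5)  # held fixed
})

test_that("fit results are internally consistent and seed-deterministic", {
  sq <- generate_trial_sequence(task_config(), seed = 51)
  p <- model_params(alpha = .4, lam = .5, eta = .7, omega = c(.3, .6, .2, .5),
                    beta = 1.5, pi = .2, rho = 0)
  ds <- simulate_agent(p, sq, seed = 52)
  f1 <- fit_map(ds, n_restarts = 5, seed = 53)
  f2 <- fit_map(ds, n_restarts = 5, seed = 53)
  expect_identical(f1$params_hat, f2$params_hat)
  expect_equal(f1$log_posterior, f1$log_likelihood + f1$log_prior,
               tolerance = 1e-8)
  expect_equal(nrow(f1$restarts), 5L)
  # more restarts can only improve the best posterior (nested restart draws)
  f4 <- fit_map(ds, n_restarts = 10, seed = 53)
  expect_gte(f4$log_posterior, f1$log_posterior - 1e-9)
  expect_equal(f4$restarts$value[1:5], f1$restarts$value[1:5])
})

test_that("with a flat likelihood the weights fall back to the prior mode", {
  sq <- generate_trial_sequence(task_config(), seed = 61)
  ds <- simulate_agent(model_params(beta = 0, pi = 0, rho = 0), sq, seed = 62)
  # with beta frozen at 0 the likelihood is exactly flat in omega, so the
  # MAP must sit at the Beta(2,2) prior mode 0.5
  fit <- fit_map(ds, n_restarts = 4, seed = 63,
                 fixed = c(beta = 0, pi = 0, rho = 0))
  om <- fit$params_hat[grepl("omega", names(fit$params_hat))]
  expect_true(all(abs(om - 0.5) < 0.01))
})

test_that("fitting refuses datasets with no valid trials", {
  ds <- random_dataset(seed = 3)
  ds$obs$miss1[] <- 1L
  expect_error(fit_map(ds, n_restarts = 2, seed = 1), "valid")
})

test_that("parameter recovery flags degenerate truth tables", {
  truth <- do.call(rbind, replicate(4, data.frame(
    participant = "p", group = "g", alpha = .5, lam = .5, eta = .7,
    omega_low_stable = .4, omega_high_stable = .4, omega_low_variable = .4,
    omega_high_variable = .4, beta = 1, pi = 0, rho = 0,
    stringsAsFactors = FALSE), simplify = FALSE))
  truth$participant <- paste0("p", 1:4)
  rec <- parameter_recovery(truth, task_config(), n_restarts = 2, seed = 9)
  expect_true(all(rec$report$degenerate))
  expect_true(all(is.na(rec$report$correlation)))
  expect_true(all(rec$report$rmse < 0.5))
})

test_that("posterior predictive reproduces a noise agent's repeat rate", {
  sq <- generate_trial_sequence(task_config(), seed = 71)
  ds <- simulate_agent(model_params(beta = 0, pi = 0, rho = 0), sq, seed = 72)
  fit <- fit_map(ds, n_restarts = 5, seed = 73)
  ppc <- posterior_predictive(fit, ds, n_sims = 30, seed = 74)
  rep_row <- ppc[ppc$statistic == "repeat_rate", ]
  expect_equal(rep_row$observed, 0.5, tolerance = 0.1)
  expect_equal(rep_row$sim_mean, 0.5, tolerance = 0.1)
  # determinism with one simulation
  p1 <- posterior_predictive(fit, ds, n_sims = 1, seed = 75)
  p2 <- posterior_predictive(fit, ds, n_sims = 1, seed = 75)
  expect_identical(p1, p2)
})

test_that("the observed statistics of a self-simulated agent sit inside the
           simulation interval most of the time", {
  sq <- generate_trial_sequence(task_config(), seed = 81)
  p <- model_params(alpha = .5, lam = .5, eta = .8, omega = .6, beta = 1.2,
                    pi = .2, rho = 0)
  fit <- list(variant = "standard", params_hat = p)
  class(fit) <- "metarl_fit"
  inside <- 0
  n_rep <- 10
  for (r in 1:n_rep) {
    ds <- simulate_agent(p, sq, seed = 900 + r)
    ppc <- posterior_predictive(fit, ds, n_sims = 40, seed = 950 + r)
    row <- ppc[ppc$statistic == "bc_reward_mean", ]
    inside <- inside + (row$observed >= row$sim_lo & row$observed <= row$sim_hi)
  }
  expect_gte(inside / n_rep, 0.8)
})

test_that("the exhaustive layout fits and expands every parameter by cell", {
  sq <- generate_trial_sequence(task_config(), seed = 55)
  ds <- simulate_agent(model_params(alpha = .5, eta = .7, omega = .5,
                                    beta = 1.2), sq, seed = 56)
  fit <- fit_map(ds, variant = "exhaustive", n_restarts = 2, seed = 57,
                 control = list(maxit = 200))
  expect_equal(length(fit$params_hat), 26L)
  expect_true(all(c("alpha_low_stable", "eta_low", "eta_high",
                    "beta_high_variable", "rho_low_variable") %in%
                    names(fit$params_hat)))
  expect_equal(fit$log_posterior, fit$log_likelihood + fit$log_prior,
               tolerance = 1e-8)
})

test_that("AIC prefers the single-rate model on single-rate data", {
  # agents generated with a single transition learning rate: the extra
  # counterfactual rate of the dual-rate variant should not pay for itself
  sq <- generate_trial_sequence(task_config(), seed = 58)
  set.seed(59)
  wins <- 0
  n_agents <- 50
  for (i in 1:n_agents) {
    p <- model_params(alpha = runif(1, .3, .7), lam = runif(1, .3, .7),
                      eta = runif(1, .4, .9), omega = runif(4, .2, .8),
                      beta = runif(1, .8, 2), pi = rnorm(1, .2, .2),
                      rho = rnorm(1, 0, .1))
    ds <- simulate_agent(p, sq, seed = 700 + i)
    f1 <- fit_map(ds, variant = "standard", n_restarts = 3, seed = 800 + i)
    f2 <- fit_map(ds, variant = "dual_transition_rate", n_restarts = 3,
                  seed = 900 + i)
    wins <- wins + (aic(f1) < aic(f2))
  }
  expect_gt(wins / n_agents, 0.5)
})
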