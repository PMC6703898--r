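#' Parameter priors for MAP estimation
#'
#' Unit-interval parameters (learning rates, eligibility-trace decay,
#' model-based weights) get a Beta(2, 2) prior, the inverse softmax
#' temperature a Gamma(3, 0.2) prior, and the stickiness parameters
#' standard-normal priors. The Gamma's second hyperparameter is interpreted
#' as a scale by default (prior mode 0.4, sensible for rewards on a 0--9
#' scale); a rate interpretation is available via
#' `gamma_parameterization = "rate"`.
#'
#' @param beta_shape1,beta_shape2 Beta prior shapes for unit parameters.
#' @param gamma_shape,gamma_par Gamma prior hyperparameters for `beta`.
#' @param gamma_parameterization `"scale"` or `"rate"`.
#' @param normal_sd Normal prior sd for unbounded parameters.
#' @return An object of class `metarl_prior_spec`.
#' @export
prior_spec <- function(beta_shape1 = 2, beta_shape2 = 2,
                       gamma_shape = 3, gamma_par = 0.2,
                       gamma_parameterization = c("scale", "rate"),
                       normal_sd = 1) {
  spec <- list(beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
               gamma_shape = gamma_shape, gamma_par = gamma_par,
               gamma_parameterization = match.arg(gamma_parameterization),
               normal_sd = normal_sd)
  class(spec) <- "metarl_prior_spec"
  spec
}

prior_density_funs <- function(priors) {
  gscale <- if (priors$gamma_parameterization == "scale") priors$gamma_par
    else 1 / priors$gamma_par
  list(
    unit = list(
      logd = function(x) stats::dbeta(x, priors$beta_shape1, priors$beta_shape2,
                                      log = TRUE),
      draw = function(n) stats::rbeta(n, priors$beta_shape1, priors$beta_shape2)),
    positive = list(
      logd = function(x) stats::dgamma(x, shape = priors$gamma_shape,
                                       scale = gscale, log = TRUE),
      draw = function(n) stats::rgamma(n, shape = priors$gamma_shape,
                                       scale = gscale)),
    real = list(
      logd = function(x) stats::dnorm(x, 0, priors$normal_sd, log = TRUE),
      draw = function(n) stats::rnorm(n, 0, priors$normal_sd)))
}

#' Log prior density of a parameter vector
#'
#' Sums the per-parameter log densities over the variant's free parameters.
#' A parameter outside its support yields `-Inf` (a rejected point), not an
#' error.
#'
#' @param theta Named parameter vector covering the variant's layout.
#' @param variant Model variant name.
#' @param priors A [prior_spec()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, variant = "standard", priors = prior_spec()) {
  lay <- variant_layout(variant)
  funs <- prior_density_funs(priors)
  v <- unname(theta[lay$name])
  if (anyNA(v)) stop("missing parameters in theta", call. = FALSE)
  total <- 0
  for (fam in unique(lay$family)) {
    x <- v[lay$family == fam]
    bad <- if (fam == "unit") x < 0 | x > 1
      else if (fam == "positive") x < 0 else rep(FALSE, length(x))
    if (any(bad)) return(-Inf)
    total <- total + sum(funs[[fam]]$logd(x))
  }
  total
}

#' Draw a parameter vector from the priors
#'
#' @inheritParams log_prior
#' @return Named numeric vector in the variant's layout.
#' @export
sample_from_prior <- function(variant = "standard", priors = prior_spec()) {
  lay <- variant_layout(variant)
  funs <- prior_density_funs(priors)
  v <- numeric(nrow(lay))
  for (fam in unique(lay$family))
    v[lay$family == fam] <- funs[[fam]]$draw(sum(lay$family == fam))
  stats::setNames(v, lay$name)
}

# Transforms between the natural (bounded) and unconstrained optimizer
# scales. The posterior is maximized on the natural scale (no Jacobian);
# the transform only keeps the search inside the support.
to_unconstrained <- function(theta, lay) {
  z <- theta
  u <- lay$family == "unit"
  p <- lay$family == "positive"
  z[u] <- stats::qlogis(pmin(pmax(theta[u], 1e-9), 1 - 1e-9))
  z[p] <- log(pmax(theta[p], 1e-12))
  z
}

to_natural <- function(z, lay) {
  theta <- z
  u <- lay$family == "unit"
  p <- lay$family == "positive"
  theta[u] <- stats::plogis(z[u])
  theta[p] <- exp(z[p])
  theta
}

# Precompute everything the per-evaluation objective needs: observation
# arrays, per-trial index maps from the flat parameter vector, and the eta
# handling (eta fixed at 1 in stable blocks).
make_loglik_fn <- function(dataset, variant) {
  arr <- obs_arrays(dataset)
  trials <- dataset$sequence$trials
  lay <- variant_layout(variant)
  n <- nrow(trials)
  cell <- cell_of(trials$stakes, trials$block_condition)
  variable <- trials$block_condition == "variable"
  q0 <- mean(dataset$sequence$config$reward_bounds)

  idx_of <- function(base) {
    if (base %in% lay$name) rep(match(base, lay$name), n)
    else match(paste0(base, "_", cell), lay$name)
  }
  i_alpha <- idx_of("alpha"); i_lam <- idx_of("lam")
  i_beta <- idx_of("beta"); i_pi <- idx_of("pi"); i_rho <- idx_of("rho")
  i_omega <- match(paste0("omega_", cell), lay$name)
  i_eta <- if (variant == "exhaustive") match(paste0("eta_", trials$stakes),
                                              lay$name)
    else rep(match("eta", lay$name), n)
  i_eta_cf <- if (variant == "dual_transition_rate")
    rep(match("eta_cf", lay$name), n) else i_eta

  function(theta) {
    eta <- ifelse(variable, theta[i_eta], 1)
    eta_cf <- ifelse(variable, theta[i_eta_cf], 1)
    hybrid_replay_cpp(arr$start_state, arr$action_local, arr$key1, arr$planet,
                      arr$reward, arr$miss1, arr$miss2, arr$left_action,
                      theta[i_alpha], theta[i_lam], eta, eta_cf,
                      theta[i_beta], theta[i_pi], theta[i_rho],
                      theta[i_omega], q0, FALSE)$loglik
  }
}

#' Maximum a posteriori fit of the hybrid model
#'
#' Maximizes `log_prior + sequence_loglik` for one participant. Bounded
#' parameters are optimized on an unconstrained scale (logit / log
#' transforms) with the prior evaluated on the natural scale; each restart
#' is initialized by a draw from the priors, run through BFGS, and the
#' restart with the highest posterior is returned. The whole procedure is
#' deterministic given `seed`, and the first `k` restarts of an
#' `n > k`-restart run coincide with a `k`-restart run at the same seed.
#'
#' @param dataset A `metarl_dataset` with at least one valid trial.
#' @param variant Model variant name (see [variant_layout()]).
#' @param priors A [prior_spec()].
#' @param n_restarts Number of random restarts (100 in the reference
#'   fitting procedure; reducible for simulation studies).
#' @param seed Optional RNG seed.
#' @param control Passed to [stats::optim()] (method BFGS); defaults to
#'   `list(maxit = 500, reltol = 1e-8)`.
#' @param fixed Optional named numeric vector of parameters held at the
#'   given values instead of being optimized; only free parameters
#'   contribute prior terms.
#' @return An object of class `metarl_fit`: list with `variant`,
#'   `params_hat` (named, natural scale), `log_posterior`,
#'   `log_likelihood`, `log_prior`, `n_restarts`, `best_restart`,
#'   `restarts` (per-restart value and convergence code) and `priors`.
#' @export
fit_map <- function(dataset, variant = "standard", priors = prior_spec(),
                    n_restarts = 100L, seed = NULL, control = list(),
                    fixed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (all(dataset$obs$miss1 == 1))
    stop("dataset has no valid first-stage responses", call. = FALSE)
  lay <- variant_layout(variant)
  loglik_fn <- make_loglik_fn(dataset, variant)
  funs <- prior_density_funs(priors)
  fam <- lay$family

  free <- if (is.null(fixed)) rep(TRUE, nrow(lay))
    else !(lay$name %in% names(fixed))
  lay_free <- lay[free, , drop = FALSE]
  full_theta <- function(theta_free) {
    theta <- numeric(nrow(lay))
    theta[free] <- theta_free
    if (!is.null(fixed)) theta[!free] <- unname(fixed[lay$name[!free]])
    theta
  }

  log_prior_v <- function(theta) {
    lp <- 0
    for (f in unique(fam)) {
      sel <- fam == f & free
      lp <- lp + sum(funs[[f]]$logd(theta[sel]))
    }
    lp
  }
  objective <- function(z) {
    theta <- full_theta(to_natural(z, lay_free))
    lp <- log_prior_v(theta) + loglik_fn(theta)
    if (!is.finite(lp)) 1e10 else -lp
  }
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-8), control)

  best <- NULL
  rows <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- unname(sample_from_prior(variant, priors))[free]
    res <- tryCatch(stats::optim(to_unconstrained(init, lay_free), objective,
                                 method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(res)) {
      rows[[r]] <- data.frame(restart = r, value = NA_real_,
                              convergence = NA_integer_)
      next
    }
    rows[[r]] <- data.frame(restart = r, value = -res$value,
                            convergence = res$convergence)
    if (is.null(best) || -res$value > best$value) {
      best <- list(value = -res$value, z = res$par, restart = r)
    }
  }
  restarts <- do.call(rbind, rows)
  if (is.null(best))
    stop("all restarts failed; see per-restart diagnostics", call. = FALSE)

  theta_hat <- stats::setNames(full_theta(to_natural(best$z, lay_free)),
                               lay$name)
  ll <- loglik_fn(unname(theta_hat))
  lp <- log_prior_v(unname(theta_hat))
  fit <- list(variant = variant, params_hat = theta_hat,
              log_posterior = ll + lp, log_likelihood = ll, log_prior = lp,
              n_restarts = n_restarts, best_restart = best$restart,
              restarts = restarts, priors = priors,
              participant_id = dataset$participant_id, group = dataset$group)
  class(fit) <- "metarl_fit"
  fit
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2 k - 2 log L` with `k` the variant's number of free parameters
#' and the likelihood evaluated at the MAP point.
#'
#' @param fit A [fit_map()] result.
#' @return Scalar AIC.
#' @export
aic <- function(fit) {
  2 * count_free_params(fit$variant) - 2 * fit$log_likelihood
}

#' Parameter recovery study
#'
#' Simulates one session per row of a ground-truth table, refits each with
#' [fit_map()], and summarizes per-parameter recovery: the correlation of
#' true and recovered values, mean bias (recovered minus true) and RMSE.
#' Parameters with (near) zero variance in the truth are flagged degenerate
#' and get `NA` correlations.
#'
#' @param truth Ground-truth table as from [draw_cohort_truth()].
#' @param config A [task_config()].
#' @param variant,priors,n_restarts,control Passed to [fit_map()].
#' @param seed RNG seed for the whole study.
#' @param sequence Optional shared trial sequence (generated from `seed` if
#'   absent).
#' @return An object of class `metarl_recovery`: list with `report` (one
#'   row per parameter), `recovered` (the per-agent fitted table) and
#'   `n_agents`.
#' @export
parameter_recovery <- function(truth, config = task_config(),
                               variant = "standard", priors = prior_spec(),
                               n_restarts = 20L, seed = 1L,
                               sequence = NULL, control = list()) {
  if (is.null(sequence))
    sequence <- generate_trial_sequence(config, seed = derive_seed(seed, "sequence"))
  lay <- variant_layout(variant)
  rec <- matrix(NA_real_, nrow(truth), nrow(lay),
                dimnames = list(NULL, lay$name))
  for (i in seq_len(nrow(truth))) {
    ds <- simulate_agent(truth_row_params(truth[i, ]), sequence,
                         seed = derive_seed(seed, paste0("sim", i)),
                         participant_id = truth$participant[i],
                         group = truth$group[i])
    fit <- fit_map(ds, variant = variant, priors = priors,
                   n_restarts = n_restarts,
                   seed = derive_seed(seed, paste0("fit", i)),
                   control = control)
    rec[i, ] <- fit$params_hat[lay$name]
  }
  common <- intersect(lay$name, names(truth))
  report <- do.call(rbind, lapply(common, function(p) {
    tv <- truth[[p]]
    rv <- rec[, p]
    degenerate <- stats::sd(tv) < 1e-10
    data.frame(parameter = p,
               correlation = if (degenerate) NA_real_ else stats::cor(tv, rv),
               bias = mean(rv - tv),
               rmse = sqrt(mean((rv - tv)^2)),
               degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  out <- list(report = report,
              recovered = data.frame(participant = truth$participant,
                                     group = truth$group, rec,
                                     stringsAsFactors = FALSE),
              n_agents = nrow(truth), variant = variant)
  class(out) <- "metarl_recovery"
  out
}

#' Posterior-predictive check for one fitted participant
#'
#' Simulates `n_sims` sessions at the fitted parameters on the same trial
#' sequence and compares observed summary statistics with the simulation
#' distribution: mean baseline-corrected reward per condition cell and
#' overall, and the first-stage repeat rate (probability of repeating the
#' previous choice when the same start state recurs).
#'
#' @param fit A [fit_map()] result (standard or dual-rate layout).
#' @param dataset The fitted participant's dataset.
#' @param n_sims Number of simulated sessions.
#' @param seed Optional RNG seed.
#' @return Data frame with one row per statistic: `observed`, `sim_mean`,
#'   `sim_lo`, `sim_hi` (2.5% and 97.5% simulation quantiles).
#' @export
posterior_predictive <- function(fit, dataset, n_sims = 100L, seed = NULL) {
  if (is.null(seed)) seed <- 1L
  stats_of <- function(ds) {
    bc <- baseline_corrected_reward(ds)
    cellv <- vapply(omega_cells(), function(cl) {
      sel <- cell_of(ds$obs$stakes, ds$obs$block_condition) == cl
      mean(bc$per_trial[sel], na.rm = TRUE)
    }, numeric(1))
    c(bc_reward_mean = bc$mean,
      stats::setNames(cellv, paste0("bc_reward_", omega_cells())),
      repeat_rate = stage1_repeat_rate(ds))
  }
  obs_stats <- stats_of(dataset)
  sims <- vapply(seq_len(n_sims), function(s) {
    ds <- simulate_agent(fit$params_hat, dataset$sequence,
                         seed = derive_seed(seed, paste0("ppc", s)))
    stats_of(ds)
  }, numeric(length(obs_stats)))
  sims <- matrix(sims, nrow = length(obs_stats))
  data.frame(statistic = names(obs_stats),
             observed = unname(obs_stats),
             sim_mean = rowMeans(sims, na.rm = TRUE),
             sim_lo = apply(sims, 1, stats::quantile, 0.025, na.rm = TRUE),
             sim_hi = apply(sims, 1, stats::quantile, 0.975, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' First-stage repeat rate
#'
#' Fraction of trials on which the previous trial's spaceship was chosen
#' again, among consecutive valid-trial pairs that share the start state.
#'
#' @param dataset A `metarl_dataset`.
#' @return Scalar proportion (`NaN` if no eligible pairs).
#' @export
stage1_repeat_rate <- function(dataset) {
  obs <- dataset$obs
  ok <- obs$miss1 == 0
  idx <- which(ok[-1] & ok[-nrow(obs)] &
                 obs$start_state[-1] == obs$start_state[-nrow(obs)]) + 1L
  mean(obs$action1[idx] == obs$action1[idx - 1L])
}
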